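# File formats: structure-factor mmCIF in/out, CCP4/MRC mode-2 maps in/out,
# reference histogram CSV, metrics CSV.

# Tokenize one mmCIF loop_ block containing _refln.* tags.
.cif_refln_block <- function(lines) {
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L; tags <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, sub("^\\s*(\\S+).*$", "\\1", lines[j]))
        j <- j + 1L
      }
      if (any(grepl("^_refln\\.", tags))) {
        rows <- character(0)
        while (j <= n && !grepl("^\\s*(loop_|_|#|data_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows <- c(rows, lines[j]); j <- j + 1L
        }
        return(list(tags = tags, rows = rows))
      }
      i <- j
    } else i <- i + 1L
  }
  NULL
}

#' Read reflections from a structure-factor mmCIF file
#'
#' Parses the `_refln` loop: Miller indices from `_refln.index_h/k/l`,
#' amplitudes from `_refln.F_meas_au` (`?` / `.` treated as missing), optional
#' `_refln.F_meas_sigma_au`, and the free flag from `_refln.status`
#' (`f` = free, `o` = observed) or `_refln.pdbx_r_free_flag` (0 = free).
#' Friedel mates, if present, are merged onto the canonical hemisphere.
#'
#' @param path File path (`.cif` / `.mmcif` / `.ent`). MTZ binary files are
#'   not supported and raise an explicit error.
#' @param cell A [unit_cell()] (required: toy SF-mmCIF files carry no cell).
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, cell) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtz")
    stop("read_reflections: MTZ is not supported; convert to structure-factor mmCIF")
  if (!ext %in% c("cif", "mmcif", "ent", "txt"))
    stop("read_reflections: unsupported format '.", ext, "'")
  blk <- .cif_refln_block(readLines(path, warn = FALSE))
  if (is.null(blk)) stop("read_reflections: no _refln loop found in ", path)
  toks <- strsplit(trimws(blk$rows), "\\s+")
  ntag <- length(blk$tags)
  bad <- vapply(toks, length, integer(1)) != ntag
  if (any(bad)) stop("read_reflections: malformed _refln row ", which(bad)[1])
  m <- do.call(rbind, toks)
  colnames(m) <- blk$tags
  need <- c("_refln.index_h", "_refln.index_k", "_refln.index_l")
  if (!all(need %in% blk$tags))
    stop("read_reflections: missing required field ",
         need[!need %in% blk$tags][1])
  if (!"_refln.F_meas_au" %in% blk$tags)
    stop("read_reflections: missing required field _refln.F_meas_au")
  hkl <- cbind(as.integer(m[, "_refln.index_h"]),
               as.integer(m[, "_refln.index_k"]),
               as.integer(m[, "_refln.index_l"]))
  fraw <- m[, "_refln.F_meas_au"]
  f <- suppressWarnings(as.numeric(ifelse(fraw %in% c("?", "."), NA, fraw)))
  sig <- if ("_refln.F_meas_sigma_au" %in% blk$tags)
    suppressWarnings(as.numeric(ifelse(m[, "_refln.F_meas_sigma_au"] %in%
                                         c("?", "."), NA,
                                       m[, "_refln.F_meas_sigma_au"])))
  else NULL
  status <- ifelse(is.na(f), "missing", "work")
  if ("_refln.status" %in% blk$tags) {
    status[m[, "_refln.status"] == "f"] <- "free"
  } else if ("_refln.pdbx_r_free_flag" %in% blk$tags) {
    status[m[, "_refln.pdbx_r_free_flag"] == "0" & !is.na(f)] <- "free"
  }
  # merge Friedel mates onto the canonical hemisphere
  flip <- hkl[, 1] < 0 | (hkl[, 1] == 0 & hkl[, 2] < 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] < 0)
  hkl[flip, ] <- -hkl[flip, , drop = FALSE]
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  keep <- !duplicated(key)
  reflection_set(hkl[keep, , drop = FALSE], f[keep], cell,
                 sigma = if (is.null(sig)) NULL else sig[keep],
                 status = status[keep])
}

#' Write reflections as structure-factor mmCIF
#'
#' @param refl A [reflection_set()].
#' @param path Output path.
#' @param data_name mmCIF data block name.
#' @export
write_reflections_cif <- function(refl, path, data_name = "toy") {
  status <- c(work = "o", free = "f", missing = "o")[refl$status]
  f <- ifelse(is.na(refl$f_obs), "?", format(refl$f_obs, digits = 9))
  sig <- ifelse(is.na(refl$sigma), "?", format(refl$sigma, digits = 6))
  status[refl$status == "missing"] <- "x"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("data_", data_name), "loop_",
               "_refln.index_h", "_refln.index_k", "_refln.index_l",
               "_refln.F_meas_au", "_refln.F_meas_sigma_au", "_refln.status",
               paste(refl$h, refl$k, refl$l, f, sig, status)), con)
  invisible(path)
}

#' Write phased amplitudes as mmCIF
#'
#' @param phases data.frame with `h,k,l,amp,phase` (degrees).
#' @param cell A [unit_cell()] (recorded in the `cell` category).
#' @param path Output path.
#' @export
write_phases_cif <- function(phases, cell, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("data_phases",
               sprintf("_cell.length_a %.4f", cell$a),
               sprintf("_cell.length_b %.4f", cell$b),
               sprintf("_cell.length_c %.4f", cell$c),
               sprintf("_cell.angle_alpha %.3f", cell$alpha),
               sprintf("_cell.angle_beta %.3f", cell$beta),
               sprintf("_cell.angle_gamma %.3f", cell$gamma),
               "loop_",
               "_refln.index_h", "_refln.index_k", "_refln.index_l",
               "_refln.F_calc_au", "_refln.phase_calc",
               paste(phases$h, phases$k, phases$l,
                     format(phases$amp, digits = 9),
                     format(phases$phase, digits = 7))), con)
  invisible(path)
}

#' Write a density map in CCP4/MRC mode-2 format
#'
#' Single-precision float data with correct cell and axis metadata
#' (column/row/section = x/y/z, full cell, origin 0).
#'
#' @param g A [density_grid()].
#' @param path Output path.
#' @export
write_map_ccp4 <- function(g, path) {
  dims <- g$spec$dims; cell <- g$spec$cell
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.vector(g$values)
  wi(dims)                      # NC NR NS
  wi(2)                         # MODE 2 = float32
  wi(c(0, 0, 0))                # NCSTART NRSTART NSSTART
  wi(dims)                      # MX MY MZ
  wf(c(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma))
  wi(c(1, 2, 3))                # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))
  wi(1)                         # ISPG (P1 frame; symmetry lives elsewhere)
  wi(0)                         # NSYMBT
  wi(rep(0, 25))                # EXTRA
  wf(c(0, 0, 0))                # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))
  wi(0)                         # NLABL
  writeBin(raw(800), con)       # labels
  wf(v)
  invisible(path)
}

#' Read a CCP4/MRC mode-2 density map
#'
#' @param path File path.
#' @return A [density_grid()] (cell taken from the header; d_min unknown and
#'   set to 3x the coarsest grid spacing).
#' @export
read_map_ccp4 <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("read_map_ccp4: only mode 2 (float32) supported")
  ri(3); mxyz <- ri(3)
  cl <- rf(6)
  ri(3); rf(3); ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  v <- rf(prod(dims))
  cell <- unit_cell(cl[1], cl[2], cl[3], cl[4], cl[5], cl[6])
  spacing <- max(c(cell$a, cell$b, cell$c) / dims)
  spec <- structure(list(dims = dims, cell = cell, d_min = 3 * spacing,
                         oversampling = 3), class = "grid_spec")
  density_grid(array(v, dims), spec)
}

#' Write a reference histogram as CSV
#' @param ref A [reference_histogram()].
#' @param path Output path.
#' @export
write_histogram_csv <- function(ref, path) {
  utils::write.csv(data.frame(value = as.numeric(ref)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a reference histogram from CSV
#' @param path CSV with a `value` column.
#' @return A [reference_histogram()].
#' @export
read_histogram_csv <- function(path) {
  reference_histogram(utils::read.csv(path)$value)
}
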