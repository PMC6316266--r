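#' Write a damage-field snapshot as a legacy VTK unstructured grid
#'
#' Exports the current state as an ASCII VTK file with one hexahedral
#' cell per element and cell-data arrays `damage` (d_P in `[0, 1]`),
#' `lambda_p` (-1 where unset) and `status` (0 interior, 1 exposed,
#' 2 removed).  Removed elements are dropped by default, mirroring
#' element deletion in the solver; `keep_removed = TRUE` keeps them
#' (with their status flag) for debugging.
#'
#' @param mesh a `voxel_mesh`.
#' @param state a `sim_state` on `mesh`.
#' @param path output file path.
#' @param keep_removed keep removed elements in the file?
#' @return `path`, invisibly.
#' @export
write_field_snapshot <- function(mesh, state, path, keep_removed = FALSE) {
  check_state(mesh, state)
  keep <- if (keep_removed) {
    seq_len(mesh$n_elements)
  } else {
    which(state$status != STATUS_REMOVED)
  }
  n <- length(keep)
  h <- mesh$Le / 2
  # 8 corners per cell in VTK_HEXAHEDRON order (bottom ccw, top ccw)
  signs <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                 c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pitcorr damage field snapshot",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", 8L * n)), con)
  if (n > 0) {
    ctr <- mesh$centers[keep, , drop = FALSE]
    pts <- matrix(0, 8L * n, 3)
    for (c8 in 1:8) {
      pts[seq(c8, by = 8L, length.out = n), ] <-
        sweep(ctr, 2, signs[c8, ] * h, "+")
    }
    writeLines(apply(pts, 1, function(p) paste(format(p, trim = TRUE),
                                               collapse = " ")), con)
  }
  writeLines(sprintf("CELLS %d %d", n, 9L * n), con)
  if (n > 0) {
    base <- (seq_len(n) - 1L) * 8L
    writeLines(vapply(base, function(b) paste(c(8L, b + 0:7), collapse = " "),
                      character(1)), con)
  }
  writeLines(sprintf("CELL_TYPES %d", n), con)
  if (n > 0) writeLines(rep("12", n), con)
  writeLines(sprintf("CELL_DATA %d", n), con)
  writeLines(c("SCALARS damage float 1", "LOOKUP_TABLE default"), con)
  if (n > 0) writeLines(format(state$dP[keep], trim = TRUE), con)
  writeLines(c("SCALARS lambda_p float 1", "LOOKUP_TABLE default"), con)
  lam <- state$lambda[keep]
  lam[is.na(lam)] <- -1
  if (n > 0) writeLines(format(lam, trim = TRUE), con)
  writeLines(c("SCALARS status int 1", "LOOKUP_TABLE default"), con)
  if (n > 0) writeLines(format(state$status[keep], trim = TRUE), con)
  invisible(path)
}

# minimal reader for round-trip tests: returns cell count and the
# named CELL_DATA arrays of a file written by write_field_snapshot()
read_field_snapshot <- function(path) {
  lines <- readLines(path)
  ncell <- as.integer(sub("^CELLS (\\d+) .*$", "\\1",
                          grep("^CELLS ", lines, value = TRUE)[1]))
  arrays <- list()
  starts <- grep("^SCALARS ", lines)
  for (s in starts) {
    name <- strsplit(lines[s], " ")[[1]][2]
    vals <- lines[(s + 2L):(s + 1L + ncell)]
    arrays[[name]] <- as.numeric(vals)
  }
  list(n_cells = ncell, arrays = arrays)
}
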