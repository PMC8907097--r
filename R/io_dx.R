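## Volumetric and tabular export of voxel fields.

#' Write a voxel field as an OpenDX scalar grid
#'
#' Standard OpenDX regular-grid format readable by common volumetric
#' viewers.  The header origin is the lower corner of voxel (0,0,0) and the
#' deltas are the voxel spacing; data order follows the DX convention (z
#' fastest).
#'
#' @param field numeric vector over voxels (linear index, x fastest).
#' @param grid the [gist_grid()].
#' @param path output file.
#' @param name dataset name written into the DX object (default from the
#'   file name).
#' @return `path`, invisibly.
#' @export
write_dx <- function(field, grid, path,
                     name = sub("\\.dx$", "", basename(path))) {
  stopifnot(length(field) == grid$n_voxels)
  d <- grid$dims
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            grid$n_voxels)), con)
  ## DX wants the last (z) index fastest; internal order has x fastest
  arr <- array(field, dim = d)
  vals <- as.vector(aperm(arr, c(3L, 2L, 1L)))
  pad <- (-length(vals)) %% 3L
  if (pad > 0L) vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.10g", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               sprintf('object "%s" class field', name),
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Counterpart of [write_dx()] for round-trip checks and for re-importing
#' exported fields.
#'
#' @param path a DX file written by [write_dx()] (regular grids only).
#' @return List: `field` (numeric vector, x fastest), `dims`, `origin`,
#'   `spacing`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  cnt <- lines[grep("gridpositions counts", lines)[1L]]
  dims <- as.integer(strsplit(sub(".*counts ", "", cnt), " ")[[1L]])
  org <- as.numeric(strsplit(sub("^origin ", "",
                                 lines[grep("^origin", lines)[1L]]),
                             " ")[[1L]])
  deltas <- lines[grep("^delta", lines)]
  sp <- as.numeric(strsplit(sub("^delta ", "", deltas[1L]), " ")[[1L]])[1L]
  i0 <- grep("data follows", lines)[1L]
  i1 <- grep("attribute", lines)[1L]
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1L):(i1 - 1L)]),
                                     "[[:space:]]+")))
  arr <- array(vals, dim = rev(dims))      # z fastest on disk
  list(field = as.vector(aperm(arr, c(3L, 2L, 1L))), dims = dims,
       origin = org, spacing = sp)
}

#' Write the per-voxel table as CSV
#'
#' One row per voxel: linear index, integer voxel coordinates, center
#' coordinates, and every supplied field column, mirroring GIST per-voxel
#' output conventions.
#'
#' @param fields named list of numeric vectors over voxels.
#' @param grid the [gist_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_voxel_csv <- function(fields, grid, path) {
  v0 <- seq_len(grid$n_voxels) - 1L
  cen <- voxel_centers(grid)
  df <- data.frame(voxel = v0 + 1L,
                   ix = v0 %% grid$dims[1],
                   iy = (v0 %/% grid$dims[1]) %% grid$dims[2],
                   iz = v0 %/% (grid$dims[1] * grid$dims[2]),
                   x = cen[, 1], y = cen[, 2], z = cen[, 3])
  for (nm in names(fields)) df[[nm]] <- fields[[nm]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
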