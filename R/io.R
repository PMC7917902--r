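## Structure and trajectory output.

#' Write a conformation to PDB or XYZ
#'
#' United atoms are written as pseudo-atoms under their element symbol
#' (CH2/CH3 appear as C).  In PDB output the structural-layer index is stored
#' in the B-factor column, so layer-coloured renderings of the adsorption
#' layer can be produced directly.
#'
#' @param conf a `conformation`.
#' @param path output file.
#' @param format `"PDB"` or `"XYZ"`.
#' @export
write_structure <- function(conf, path, format = c("PDB", "XYZ")) {
  format <- match.arg(format)
  topo <- conf$topology
  x <- conf$coords
  if (format == "XYZ") {
    write_xyz_frame(topo$atoms$element, x, path,
                    comment = sprintf("%s G%d dendrimer", topo$spec$series,
                                      topo$spec$generation))
  } else {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(x)),
      type = rep("ATOM", topo$N),
      eleno = topo$atoms$id,
      elety = topo$atoms$element,
      resid = rep("DND", topo$N),
      chain = rep("A", topo$N),
      resno = rep(1L, topo$N),
      o = rep(1, topo$N),
      b = as.numeric(topo$atoms$layer),
      elesy = topo$atoms$element)
  }
  invisible(path)
}

write_xyz_frame <- function(elements, coords, path, comment = "", append = FALSE) {
  lines <- c(as.character(length(elements)), comment,
             sprintf("%-2s %12.6f %12.6f %12.6f", elements,
                     coords[, 1L], coords[, 2L], coords[, 3L]))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Read a (single- or multi-frame) XYZ file
#'
#' @param path XYZ file.
#' @return list of frames, each with `elements` and `coords` (N x 3).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- as.integer(trimws(lines[pos]))
    block <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    frames[[length(frames) + 1L]] <- list(
      elements = vapply(tok, `[[`, character(1), 1L),
      coords = matrix(as.numeric(unlist(lapply(tok, `[`, 2:4))),
                      ncol = 3L, byrow = TRUE))
    pos <- pos + 2L + n
  }
  frames
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param every write every `every`-th stored frame.
#' @export
write_xyz_trajectory <- function(traj, path, every = 1L) {
  el <- traj$topology$atoms$element
  idx <- seq(1L, n_frames(traj), by = every)
  first <- TRUE
  for (i in idx) {
    write_xyz_frame(el, traj$coords[, , i], path,
                    comment = sprintf("t = %g ps", traj$times[i]),
                    append = !first)
    first <- FALSE
  }
  invisible(path)
}
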