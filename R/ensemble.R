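## Ensemble data model I/O and windowing.
##
## On-disk dialect:
##  - coordinates: multi-model PDB, one MODEL per frame, CA records only,
##    chains labelled A, B, ... (read back with bio3d);
##  - metadata: TSV with header `frame_index traj_id step temp_index energy`
##    (frame_index and temp_index 0-based in files, stated in the header
##    comment; converted to 1-based in memory);
##  - ladder/box/system constants: key=value config text.

#' Minimum-image distance in a cubic periodic box
#'
#' Euclidean distance between two points under the cubic minimum-image
#' convention; never exceeds (sqrt(3)/2) * side.
#'
#' @param a,b numeric xyz vectors (Angstrom).
#' @param box a [BoxSpec-class] with \code{periodic = TRUE}.
#' @return distance in Angstrom.
#' @examples
#' minImageDistance(c(1, 1, 1), c(99, 99, 99), boxSpec(100))  # sqrt(12)
#' @export
minImageDistance <- function(a, b, box) {
  if (!box@periodic) stop("minimum image requires a periodic box")
  d <- a - b
  d <- d - box@side * round(d / box@side)
  sqrt(sum(d * d))
}

## all pairwise min-image distances between rows of two coordinate matrices
minImageCrossDist <- function(A, B, box) {
  side <- box@side
  out <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- d - side * round(d / side)
    out <- out + d * d
  }
  sqrt(out)
}

#' Restrict an ensemble to the analysis window
#'
#' Per trajectory, keeps the final \code{windowFrames} frames and then every
#' \code{stride}-th of those (frames \code{stride, 2*stride, ...} within the
#' window), mirroring the convention of analysing the last segment of each
#' replica-exchange trajectory with sub-sampling.  The resulting count is
#' \code{nTraj * windowFrames / stride}.
#'
#' @param ensemble an [EnsembleSet-class].
#' @param windowFrames frames kept (from the end) per trajectory
#'   (default 1000).
#' @param stride sub-sampling stride within the window (default 8).
#' @return A windowed [EnsembleSet-class].
#' @export
analysisWindow <- function(ensemble, windowFrames = 1000L, stride = 8L) {
  meta <- ensemble@meta
  keep <- integer(0)
  for (tr in sort(unique(meta$traj))) {
    idx <- which(meta$traj == tr)
    idx <- idx[order(meta$step[idx])]
    if (length(idx) < windowFrames)
      stop("trajectory ", tr, " has only ", length(idx),
           " frames (< windowFrames = ", windowFrames, ")")
    win <- utils::tail(idx, windowFrames)
    keep <- c(keep, win[seq(stride, windowFrames, by = stride)])
  }
  keep <- sort(keep)
  ensembleSet(ensemble@coords[keep], meta[keep, , drop = FALSE],
              ensemble@ladder, ensemble@box, ensemble@energyUnit)
}

#' Write an ensemble to disk
#'
#' Writes the multi-model CA-trace PDB, the metadata TSV and the config file
#' under a common path prefix (\code{<prefix>.pdb}, \code{<prefix>.tsv},
#' \code{<prefix>.cfg}).
#'
#' @param ensemble an [EnsembleSet-class].
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
writeEnsemble <- function(ensemble, prefix) {
  pdb_path <- paste0(prefix, ".pdb")
  meta_path <- paste0(prefix, ".tsv")
  cfg_path <- paste0(prefix, ".cfg")

  con <- file(pdb_path, "w")
  on.exit(close(con), add = TRUE)
  chains <- LETTERS[seq_len(ensemble@nChains)]
  for (fi in seq_along(ensemble@coords)) {
    writeLines(sprintf("MODEL     %4d", fi), con)
    frame <- ensemble@coords[[fi]]
    serial <- 0L
    for (ci in seq_along(frame)) {
      xyz <- frame[[ci]]
      for (ri in seq_len(nrow(xyz))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, chains[ci], ri, xyz[ri, 1], xyz[ri, 2], xyz[ri, 3]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)

  meta <- ensemble@meta
  out <- data.frame(frame_index = seq_len(nrow(meta)) - 1L,
                    traj_id = meta$traj, step = meta$step,
                    temp_index = meta$tempIndex - 1L,
                    energy = meta$energy)
  meta_con <- file(meta_path, "w")
  writeLines(c("# frame_index and temp_index are 0-based",
               paste0("# energy_unit=", ensemble@energyUnit)), meta_con)
  close(meta_con)
  suppressWarnings(utils::write.table(
    out, meta_path, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))

  writeLines(c(
    paste0("ladder=", paste(ensemble@ladder, collapse = ",")),
    paste0("box_side=", ensemble@box@side),
    paste0("periodic=", as.integer(ensemble@box@periodic)),
    paste0("n_chains=", ensemble@nChains),
    paste0("residues_per_chain=", ensemble@residuesPerChain),
    paste0("energy_unit=", ensemble@energyUnit)), cfg_path)

  invisible(c(pdb = pdb_path, meta = meta_path, cfg = cfg_path))
}

readConfig <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) paste(x[-1L], collapse = "=")),
                  vapply(kv, `[[`, character(1), 1L))
}

#' Read an ensemble from disk
#'
#' Reads the multi-model CA PDB, joins frames 1:1 to metadata rows by
#' \code{frame_index}, and computes the per-ladder-temperature sample counts.
#'
#' @param coordPath multi-model PDB path (CA records, one MODEL per frame).
#' @param metaPath metadata TSV path (columns \code{frame_index},
#'   \code{traj_id}, \code{step}, \code{temp_index}, \code{energy};
#'   frame_index and temp_index 0-based).
#' @param configPath config file path carrying the ladder and box
#'   (defaults to \code{metaPath} with extension \code{.cfg}).
#' @return An [EnsembleSet-class].
#' @export
readEnsemble <- function(coordPath, metaPath,
                         configPath = sub("\\.[^.]*$", ".cfg", metaPath)) {
  cfg <- readConfig(configPath)
  ladder <- as.numeric(strsplit(cfg$ladder, ",")[[1L]])
  box <- boxSpec(as.numeric(cfg$box_side),
                 periodic = as.integer(cfg$periodic) == 1L)
  nChains <- as.integer(cfg$n_chains)
  nRes <- as.integer(cfg$residues_per_chain)
  unit <- if (is.null(cfg$energy_unit)) "kcal/mol" else cfg$energy_unit

  pdb <- bio3d::read.pdb(coordPath, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_atoms <- ncol(xyz) / 3L
  if (n_atoms != nChains * nRes)
    stop("coordinate file has ", n_atoms, " atoms per model, expected ",
         nChains * nRes)
  coords <- lapply(seq_len(nrow(xyz)), function(fi) {
    fr <- matrix(xyz[fi, ], ncol = 3L, byrow = TRUE)
    lapply(seq_len(nChains), function(ci) {
      fr[((ci - 1L) * nRes + 1L):(ci * nRes), , drop = FALSE]
    })
  })

  meta_raw <- utils::read.delim(metaPath, comment.char = "#",
                                stringsAsFactors = FALSE)
  need <- c("frame_index", "traj_id", "step", "temp_index", "energy")
  if (!all(need %in% names(meta_raw)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  if (nrow(meta_raw) != length(coords))
    stop("frame/metadata count mismatch: ", length(coords), " models vs ",
         nrow(meta_raw), " metadata rows")
  meta_raw <- meta_raw[order(meta_raw$frame_index), , drop = FALSE]
  if (any(meta_raw$temp_index < 0L | meta_raw$temp_index >= length(ladder)))
    stop("temp_index out of range for a ", length(ladder), "-rung ladder")
  if (any(!is.finite(meta_raw$energy))) stop("non-finite energy in metadata")
  meta <- data.frame(traj = meta_raw$traj_id, step = meta_raw$step,
                     tempIndex = meta_raw$temp_index + 1L,
                     energy = meta_raw$energy)
  ensembleSet(coords, meta, ladder, box, unit)
}
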