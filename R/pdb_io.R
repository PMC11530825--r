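#' Read a (multi-model) PDB file into an ensemble
#'
#' One frame per MODEL record; a plain ATOM-only file yields a single
#' frame. Residues are renumbered to a contiguous 1-based internal
#' scheme in order of first appearance; region labels are then taken
#' from `region_map` over those internal indices (by default the
#' ASO 1-10 / hairpin 11-42 profile when the residue count fits).
#' Parsing is delegated to `bio3d::read.pdb`; the file is pre-scanned so
#' that a model with a deviant atom count is reported by model number.
#'
#' @param path PDB file path, or a character vector of PDB lines.
#' @param region_map Optional region mapping (see [build_topology()]).
#' @param times Optional frame times in ns.
#' @param o2prime_role Passed to [build_topology()].
#' @return An `"ensemble"`.
#' @export
read_multimodel_pdb <- function(path, region_map = NULL, times = NULL,
                                o2prime_role = "backbone") {
  if (length(path) == 1L && file.exists(path)) {
    lines <- readLines(path)
    file <- path
  } else {
    lines <- path
    file <- tempfile(fileext = ".pdb")
    writeLines(lines, file)
    on.exit(unlink(file))
  }
  is_atom <- grepl("^ATOM  |^HETATM", lines)
  if (!any(is_atom)) stop("no ATOM records found")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("MODEL/ENDMDL records unbalanced")
    counts <- mapply(function(s, e) sum(is_atom[s:e]),
                     model_starts, model_ends)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop("model ", bad, " has ", counts[bad],
           " atoms; expected ", counts[1], " as in model 1")
    }
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  resid <- toupper(trimws(at$resid))
  resid[resid %in% c("RA", "ADE", "RA3", "RA5")] <- "A"
  resid[resid %in% c("RC", "CYT", "RC3", "RC5")] <- "C"
  resid[resid %in% c("RG", "GUA", "RG3", "RG5")] <- "G"
  resid[resid %in% c("RU", "URA", "RU3", "RU5")] <- "U"
  bad <- setdiff(unique(resid), c("A", "C", "G", "U"))
  if (length(bad))
    stop("unsupported (non-nucleotide) residue(s): ",
         paste(bad, collapse = ", "))
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  res_key <- paste(chain, at$resno)
  internal <- match(res_key, unique(res_key))
  first <- !duplicated(internal)
  residues <- data.frame(residue_index = internal[first],
                         nucleotide = resid[first],
                         chain_label = chain[first])
  if (is.null(region_map) &&
      nrow(residues) == 42L) region_map <- aso_hairpin_regions()
  atoms <- data.frame(atom_name = trimws(at$elety),
                      residue_index = internal)
  topo <- build_topology(residues, atoms, region_map = region_map,
                         o2prime_role = o2prime_role)
  xyz_mat <- pdb$xyz
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1L)
  nf <- nrow(xyz_mat)
  na <- ncol(xyz_mat) / 3L
  xyz <- array(0, dim = c(nf, na, 3L))
  for (k in 1:3) xyz[, , k] <- xyz_mat[, seq(k, by = 3L,
                                             length.out = na), drop = FALSE]
  new_ensemble(topo, xyz, times = times)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at the format's fixed 3-decimal precision, so
#' a write/read round trip reproduces them to 1e-3 Angstrom.
#'
#' @param ensemble An `"ensemble"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  topo <- ensemble$topology
  at <- topo$atoms
  res <- topo$residues
  chain <- res$chain_label[match(at$residue_index, res$residue_index)]
  nuc <- at$nucleotide
  name_field <- ifelse(nchar(at$atom_name) >= 4L, at$atom_name,
                       paste0(" ", at$atom_name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_xyz(ensemble, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), name_field, nuc, substr(chain, 1, 1),
      at$residue_index, m[, 1], m[, 2], m[, 3], 1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
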