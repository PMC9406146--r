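## Sequence-level descriptors: GRAVY hydropathy, Henderson-Hasselbalch net
## charge, and the cubic box side matching a molar concentration.

validateSequence <- function(sequence, context = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0)
    stop(context, " must be a single non-empty string")
  aa <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(aa, names(kyteDoolittle()))
  if (length(bad))
    stop("invalid residue letter '", bad[1L], "' in ", context, " '",
         sequence, "'")
  aa
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean per-residue hydropathy index over a sequence.  Positive values are
#' hydrophobic.  Terminal modifications do not enter the value, and GRAVY is
#' invariant under any permutation of the sequence.
#'
#' @param sequence one-letter amino-acid string (20 canonical letters).
#' @param scale named per-residue hydropathy indices; default
#'   [kyteDoolittle()].
#' @return Dimensionless numeric scalar.
#' @examples
#' computeGravy("ARKQIV")   # -0.2333...
#' computeGravy("GNNQQNY")  # -2.7428...
#' @export
computeGravy <- function(sequence, scale = kyteDoolittle()) {
  aa <- validateSequence(sequence)
  missing_scale <- setdiff(aa, names(scale))
  if (length(missing_scale))
    stop("hydropathy scale lacks residue '", missing_scale[1L], "'")
  mean(scale[aa])
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: each basic group
#' contributes \code{1/(1 + 10^(pH - pKa))} and each acidic group
#' \code{-1/(1 + 10^(pKa - pH))}.  The N-terminal amine term is included only
#' for a free N-terminus, the C-terminal carboxyl only for a free-acid
#' C-terminus; acetylated/amidated termini contribute nothing.
#'
#' @param sequence one-letter amino-acid string.
#' @param pH pH value in (0, 14); default 7.
#' @param nTerm one of "free", "acetyl".
#' @param cTerm one of "free-acid", "amide".
#' @param pka pKa set as returned by [defaultPka()] (injectable).
#' @return Net charge in elementary charges.
#' @examples
#' computeNetCharge("RDKVYRGGGAAPVGGGRDKVYR", nTerm = "acetyl",
#'                  cTerm = "amide")  # ~4.0
#' @export
computeNetCharge <- function(sequence, pH = 7,
                             nTerm = c("free", "acetyl"),
                             cTerm = c("free-acid", "amide"),
                             pka = defaultPka()) {
  nTerm <- match.arg(nTerm)
  cTerm <- match.arg(cTerm)
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  if (any(pka$pKa <= 0 | pka$pKa >= 14)) stop("pKa values must lie in (0, 14)")
  aa <- validateSequence(sequence)
  counts <- table(factor(aa, levels = pka$group))
  charge <- 0
  for (g in seq_len(nrow(pka))) {
    grp <- pka$group[g]
    n_grp <- if (grp == "nterm") {
      as.numeric(nTerm == "free")
    } else if (grp == "cterm") {
      as.numeric(cTerm == "free-acid")
    } else {
      as.numeric(counts[[grp]])
    }
    if (n_grp == 0) next
    if (pka$basic[g]) {
      charge <- charge + n_grp / (1 + 10^(pH - pka$pKa[g]))
    } else {
      charge <- charge - n_grp / (1 + 10^(pka$pKa[g] - pH))
    }
  }
  charge
}

#' Cubic box side matching a molar concentration
#'
#' Side length of the cubic periodic box in which \code{nChains} copies of a
#' peptide reproduce the experimental molar concentration:
#' \code{side = (nChains / (C * N_A))^(1/3)}, converted to Angstrom
#' (N_A = 6.02214076e23 exactly).
#'
#' @param concentration peptide concentration in millimolar (> 0).
#' @param nChains number of simulated chains (>= 1).
#' @return Box side in Angstrom.
#' @examples
#' boxSideForConcentration(4.210, 8)   # 146.7 A
#' @export
boxSideForConcentration <- function(concentration, nChains = 8L) {
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be positive")
  if (nChains < 1) stop("nChains must be >= 1")
  ## volume in A^3: nChains molecules / (C[mol/L] * N_A [1/mol]) * 1e27 A^3/L
  vol <- nChains * 1e30 / (concentration * AVOGADRO)
  vol^(1 / 3)
}

#' Read a peptide table (delimited text or FASTA)
#'
#' Delimited files must have a header naming the columns \code{name},
#' \code{sequence}, \code{n_term}, \code{c_term}, \code{concentration_mM}.
#' FASTA input is also accepted (headers carry the name; termini default to
#' free / free-acid and the concentration to NA).
#'
#' @param path file path.
#' @return data.frame with one row per peptide, order preserved, columns
#'   name, sequence, n_term, c_term, concentration_mM.
#' @export
readPeptideTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    warning("empty peptide table: ", path)
    return(data.frame(name = character(0), sequence = character(0),
                      n_term = character(0), c_term = character(0),
                      concentration_mM = numeric(0),
                      stringsAsFactors = FALSE))
  }
  is_fasta <- grepl("^>", first) ||
    grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)
  if (is_fasta) {
    seqs <- Biostrings::readAAStringSet(path)
    tab <- data.frame(name = sub("\\s.*$", "", names(seqs)),
                      sequence = as.character(seqs),
                      n_term = "free", c_term = "free-acid",
                      concentration_mM = NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
    need <- c("name", "sequence", "n_term", "c_term", "concentration_mM")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols))
      stop("peptide table lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    tab <- tab[, need]
    tab$concentration_mM <- suppressWarnings(
      as.numeric(tab$concentration_mM))
    bad_num <- which(is.na(tab$concentration_mM))
    if (length(bad_num))
      stop("unparsable concentration at row ", bad_num[1L])
  }
  dup <- which(duplicated(tab$name))
  if (length(dup)) stop("duplicate peptide name at row ", dup[1L],
                        ": ", tab$name[dup[1L]])
  for (r in seq_len(nrow(tab))) {
    tryCatch(validateSequence(tab$sequence[r]),
             error = function(e) stop("row ", r, ": ", conditionMessage(e)))
    if (!tab$n_term[r] %in% c("free", "acetyl"))
      stop("row ", r, ": n_term must be free or acetyl")
    if (!tab$c_term[r] %in% c("free-acid", "amide"))
      stop("row ", r, ": c_term must be free-acid or amide")
  }
  rownames(tab) <- NULL
  tab
}

#' Descriptor table for a set of peptides
#'
#' Computes, per peptide, the residue count, GRAVY, net charge at the given
#' pH and the cubic box side matching its concentration for \code{nChains}
#' chains.  Values are reported both raw and rounded (half away from zero) at
#' reference-table precision: 3 decimals for GRAVY, 1 for charge, 0.1 A for
#' the box side.
#'
#' @param peptides data.frame as returned by [readPeptideTable()].
#' @param pH pH for the charge (default 7).
#' @param nChains chains for the box sizing (default 8).
#' @param pka injectable pKa set.
#' @param scale injectable hydropathy scale.
#' @return data.frame with columns name, sequence, n, gravy, charge,
#'   concentration_mM, box_side plus rounded gravy3, charge1, box_side1.
#' @export
descriptorTable <- function(peptides, pH = 7, nChains = 8L,
                            pka = defaultPka(), scale = kyteDoolittle()) {
  gravy <- vapply(peptides$sequence, computeGravy, numeric(1), scale = scale)
  charge <- mapply(computeNetCharge, peptides$sequence,
                   nTerm = peptides$n_term, cTerm = peptides$c_term,
                   MoreArgs = list(pH = pH, pka = pka))
  side <- vapply(peptides$concentration_mM,
                 function(cc) if (is.na(cc)) NA_real_ else
                   boxSideForConcentration(cc, nChains), numeric(1))
  data.frame(
    name = peptides$name, sequence = peptides$sequence,
    n = nchar(peptides$sequence),
    gravy = unname(gravy), charge = unname(charge),
    concentration_mM = peptides$concentration_mM,
    box_side = unname(side),
    gravy3 = roundHalfAway(unname(gravy), 3),
    charge1 = roundHalfAway(unname(charge), 1),
    box_side1 = roundHalfAway(unname(side), 1),
    stringsAsFactors = FALSE)
}
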