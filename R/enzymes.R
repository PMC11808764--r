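# In-silico enzymatic digestion: cleavage specificities, missed-cleavage
# handling, monoisotopic mass / m/z computation, FASTA input.

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Define a proteolytic enzyme specificity
#'
#' An enzyme is described by the set of residues it recognises and the side
#' of the matched residue at which the peptide bond is hydrolysed.
#'
#' @param name Text label for the enzyme.
#' @param target_residues Character vector of one-letter amino-acid codes the
#'   enzyme cleaves at. Must be a non-empty subset of the 20 standard codes.
#' @param cut_side `"C_TERMINAL"` to cut after the matched residue (trypsin
#'   style) or `"N_TERMINAL"` to cut before it (Asp-N style).
#'
#' @return An object of class `enzyme_spec`.
#' @seealso [builtin_enzymes()] for the five specificities bundled with the
#'   package.
#' @export
enzyme_spec <- function(name, target_residues,
                        cut_side = c("C_TERMINAL", "N_TERMINAL")) {
  cut_side <- match.arg(cut_side)
  target_residues <- unique(toupper(target_residues))
  if (length(target_residues) == 0L)
    stop("enzyme_spec: 'target_residues' must be non-empty", call. = FALSE)
  bad <- setdiff(target_residues, AA_CODES)
  if (length(bad) > 0L)
    stop("enzyme_spec: non-standard residue code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name,
                 target_residues = target_residues,
                 cut_side = cut_side),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s: cuts %s-terminal of {%s}\n", x$name,
              if (x$cut_side == "C_TERMINAL") "C" else "N",
              paste(sort(x$target_residues), collapse = ",")))
  invisible(x)
}

#' Built-in enzyme specificities
#'
#' The five specificities used throughout the package. Trypsin cleaves
#' C-terminal of the basic residues Lys and Arg; Arg-C C-terminal of Arg;
#' Glu-C C-terminal of Glu and Asp; Asp-N N-terminal of Asp; chymotrypsin
#' C-terminal of the eight residues Ala, Asp, Glu, Leu, Met, Phe, Tyr, Trp.
#' No proline-suppression rule is applied (see the methods vignette for why
#' this chymotrypsin definition differs from some common ones).
#'
#' @return A named list of [enzyme_spec()] objects with names `trypsin`,
#'   `arg_c`, `glu_c`, `asp_n`, `chymotrypsin`.
#' @examples
#' builtin_enzymes()[["trypsin"]]
#' @export
builtin_enzymes <- function() {
  list(
    trypsin      = enzyme_spec("trypsin", c("K", "R"), "C_TERMINAL"),
    arg_c        = enzyme_spec("arg_c", "R", "C_TERMINAL"),
    glu_c        = enzyme_spec("glu_c", c("E", "D"), "C_TERMINAL"),
    asp_n        = enzyme_spec("asp_n", "D", "N_TERMINAL"),
    chymotrypsin = enzyme_spec("chymotrypsin",
                               c("A", "D", "E", "L", "M", "F", "Y", "W"),
                               "C_TERMINAL")
  )
}

check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string", call. = FALSE)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_CODES)
  if (length(bad) > 0L)
    stop("non-standard residue(s) in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  chars
}

#' Locate cleavage sites in a protein sequence
#'
#' Cut indices are 0-based: a site `s` means the bond between residues
#' `s` and `s + 1` (1-based) is hydrolysed, i.e. the sequence is cut
#' between positions `s - 1` and `s` in 0-based coordinates. Sites at the
#' ends of the chain (0 and the sequence length) are never reported.
#'
#' @param sequence Protein sequence (standard one-letter codes only).
#' @param enzyme An [enzyme_spec()].
#' @return Strictly increasing integer vector of cut indices, possibly empty.
#' @examples
#' cleavage_sites("AKRGG", builtin_enzymes()$trypsin) # 2, 3
#' @export
cleavage_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  chars <- check_sequence(sequence)
  L <- length(chars)
  hits <- which(chars %in% enzyme$target_residues)
  s <- if (enzyme$cut_side == "C_TERMINAL") hits else hits - 1L
  sort(unique(s[s >= 1L & s <= L - 1L]))
}

#' Digest a protein sequence in silico
#'
#' Enumerates every peptide spanning `m + 1` consecutive fully-cleaved
#' fragments for `0 <= m <= max_missed`, tagging each with its
#' missed-cleavage count. Coordinates are 0-based half-open, so
#' `substr(sequence, start + 1, end)` recovers the peptide.
#'
#' @param sequence Protein sequence.
#' @param enzyme An [enzyme_spec()].
#' @param max_missed Maximum number of internal missed cleavage sites
#'   (default 2, the usual database-search setting).
#' @param parent_id Optional protein identifier carried into the result.
#' @return A data.frame with columns `parent_id`, `start`, `end`,
#'   `sequence`, `missed_cleavages`.
#' @examples
#' digest("AKGGRCC", builtin_enzymes()$trypsin, max_missed = 1)
#' @export
digest <- function(sequence, enzyme, max_missed = 2L, parent_id = NA_character_) {
  if (max_missed < 0L) stop("max_missed must be >= 0", call. = FALSE)
  sites <- cleavage_sites(sequence, enzyme)
  L <- nchar(sequence)
  bounds <- c(0L, sites, L)
  nb <- length(bounds)
  out <- vector("list", max_missed + 1L)
  for (m in 0:max_missed) {
    # peptide spans bounds[i] .. bounds[i + m + 1]
    if (nb < m + 2L) break
    i <- seq_len(nb - m - 1L)
    out[[m + 1L]] <- data.frame(
      parent_id = parent_id,
      start = bounds[i],
      end = bounds[i + m + 1L],
      missed_cleavages = m,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  res$sequence <- substring(sequence, res$start + 1L, res$end)
  rownames(res) <- NULL
  res[, c("parent_id", "start", "end", "sequence", "missed_cleavages")]
}

#' Monoisotopic residue mass table
#'
#' Residue (amino-acid minus water) monoisotopic masses in Da for the 20
#' standard residues, plus the water and proton masses needed to place a
#' peptide on the m/z axis.
#'
#' @return A list with elements `residue_mass` (named numeric, Da),
#'   `water_mass` and `proton_mass`.
#' @export
mass_table <- function() {
  list(
    residue_mass = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
      T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
      N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
      E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
      R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    water_mass = 18.01056,
    proton_mass = 1.00728
  )
}

#' Monoisotopic peptide mass and m/z
#'
#' `peptide_mass()` returns the neutral monoisotopic mass; `peptide_mz()`
#' the m/z of the `[M + zH]^z+` ion.
#'
#' @param sequence Peptide sequence(s); vectorised.
#' @param charge Positive integer charge state.
#' @param masses A [mass_table()].
#' @return Numeric vector (Da, respectively Th).
#' @examples
#' peptide_mz("G", 1) # 76.0393
#' @export
peptide_mz <- function(sequence, charge, masses = mass_table()) {
  if (any(charge < 1L)) stop("charge must be >= 1", call. = FALSE)
  (peptide_mass(sequence, masses) + charge * masses$proton_mass) / charge
}

#' @rdname peptide_mz
#' @export
peptide_mass <- function(sequence, masses = mass_table()) {
  vapply(sequence, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), names(masses$residue_mass))
    if (length(bad) > 0L)
      stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
    sum(masses$residue_mass[chars]) + masses$water_mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a protein FASTA file
#'
#' @param path Path to a (possibly line-wrapped, multi-record) FASTA file.
#' @return Named character vector of amino-acid sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write protein sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Digest every protein in a FASTA-style set
#'
#' @param seqs Named character vector (e.g. from [read_protein_fasta()]).
#' @param enzyme An [enzyme_spec()].
#' @param max_missed Maximum missed cleavages.
#' @return One data.frame of peptides over all parents, with a `mass`
#'   column (neutral monoisotopic, Da).
#' @export
digest_proteome <- function(seqs, enzyme, max_missed = 2L) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("protein_", seq_along(seqs))
  res <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    digest(seqs[[i]], enzyme, max_missed, parent_id = ids[i])
  }))
  res$mass <- peptide_mass(res$sequence)
  rownames(res) <- NULL
  res
}

#' Write a peptide table as TSV
#'
#' @param peptides Data.frame from [digest_proteome()] or [digest()].
#' @param path Output path.
#' @export
write_peptides_tsv <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
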