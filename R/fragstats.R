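# Normalized b/y fragment-ion count and intensity statistics as a
# function of CE shift, and their curve maxima.

#' Parse a fragment-annotation string
#'
#' Annotations travel in the PSM TSV as semicolon-joined
#' `type:index:intensity` triples, e.g. `"y:3:1200;b:2:90"`. Fragment
#' charge states are not distinguished.
#'
#' @param s Annotation string (may be empty).
#' @return Data.frame with columns `type` (`"b"`/`"y"`), `index`,
#'   `intensity`; zero rows for an empty string.
#' @export
parse_fragments <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(type = character(), index = integer(),
                      intensity = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(type = tolower(vapply(parts, `[[`, character(1), 1L)),
             index = as.integer(vapply(parts, `[[`, character(1), 2L)),
             intensity = as.numeric(vapply(parts, `[[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Format a fragment data.frame back to the annotation string
#'
#' @param frags Data.frame as returned by [parse_fragments()].
#' @return Single string.
#' @export
format_fragments <- function(frags) {
  if (nrow(frags) == 0L) return("")
  paste(sprintf("%s:%d:%.6g", frags$type, frags$index, frags$intensity),
        collapse = ";")
}

#' Normalized b/y fragment counts for one PSM
#'
#' Counts of distinct b and y indices, each divided by the maximum
#' possible number of fragments of that series, `L - 1` for a peptide of
#' length `L`.
#'
#' @param fragments Fragment data.frame or annotation string.
#' @param peptide_length Length of the matched peptide (>= 2).
#' @return Named numeric `c(b = , y = )`, both in [0, 1].
#' @export
normalized_counts <- function(fragments, peptide_length) {
  if (is.character(fragments)) fragments <- parse_fragments(fragments)
  if (nrow(fragments) == 0L)
    stop("normalized_counts: no fragment annotations", call. = FALSE)
  stopifnot(peptide_length >= 2L)
  denom <- peptide_length - 1L
  if (any(fragments$index > denom))
    stop("fragment index exceeds peptide length - 1", call. = FALSE)
  count <- function(tp) length(unique(fragments$index[fragments$type == tp]))
  c(b = count("b") / denom, y = count("y") / denom)
}

#' Normalized b/y fragment intensities for one PSM
#'
#' Summed fragment intensities per series, divided by the precursor ion
#' intensity so each PSM contributes with the same weight.
#'
#' @param fragments Fragment data.frame or annotation string.
#' @param precursor_intensity Precursor intensity (> 0).
#' @return Named numeric `c(b = , y = )`, non-negative.
#' @export
normalized_intensities <- function(fragments, precursor_intensity) {
  if (is.character(fragments)) fragments <- parse_fragments(fragments)
  if (!is.finite(precursor_intensity) || precursor_intensity <= 0)
    stop("normalized_intensities: precursor intensity must be > 0",
         call. = FALSE)
  total <- function(tp) sum(fragments$intensity[fragments$type == tp])
  c(b = total("b") / precursor_intensity,
    y = total("y") / precursor_intensity)
}

#' Average normalized b/y curves as a function of CE shift
#'
#' Computes per-PSM normalized counts and intensities and averages them,
#' unweighted, over all PSMs at each CE offset. Offsets with no annotated
#' PSM are omitted. Charges are pooled by default; pass a `charges`
#' subset for a per-charge breakdown.
#'
#' @param psms PSM data.frame with non-empty `fragments` for the PSMs to
#'   include.
#' @param charges Optional integer vector restricting precursor charges.
#' @return Data.frame (`offset`, `ion_type`, `statistic`, `mean`, `n`)
#'   with `statistic` in `{"COUNT", "INTENSITY"}`; COUNT means lie in
#'   [0, 1].
#' @export
average_curves <- function(psms, charges = NULL) {
  psms <- check_psm_table(psms)
  if (!is.null(charges)) psms <- psms[psms$charge %in% charges, , drop = FALSE]
  psms <- psms[nzchar(psms$fragments), , drop = FALSE]
  if (nrow(psms) == 0L)
    return(data.frame(offset = numeric(), ion_type = character(),
                      statistic = character(), mean = numeric(),
                      n = integer()))
  per_psm <- do.call(rbind, lapply(seq_len(nrow(psms)), function(i) {
    fr <- parse_fragments(psms$fragments[i])
    cts <- normalized_counts(fr, nchar(psms$peptide[i]))
    ints <- normalized_intensities(fr, psms$precursor_intensity[i])
    data.frame(offset = psms$offset[i],
               b_count = cts[["b"]], y_count = cts[["y"]],
               b_intensity = ints[["b"]], y_intensity = ints[["y"]])
  }))
  agg <- function(col, ion, stat) {
    m <- tapply(per_psm[[col]], per_psm$offset, mean)
    data.frame(offset = as.numeric(names(m)), ion_type = ion,
               statistic = stat, mean = as.numeric(m),
               n = as.integer(table(per_psm$offset)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(agg("b_count", "b", "COUNT"), agg("y_count", "y", "COUNT"),
               agg("b_intensity", "b", "INTENSITY"),
               agg("y_intensity", "y", "INTENSITY"))
  out[order(out$statistic, out$ion_type, out$offset), , drop = FALSE]
}

#' Offset at which a shift curve peaks
#'
#' @param curve Subset of an [average_curves()] result for one ion type
#'   and statistic (>= 3 points). Ties resolve to the smaller offset.
#' @return The offset (eV) of the curve maximum.
#' @export
curve_peak_offset <- function(curve) {
  if (nrow(curve) < 3L)
    stop("curve_peak_offset: need >= 3 points", call. = FALSE)
  if (length(unique(paste(curve$ion_type, curve$statistic))) != 1L)
    stop("curve_peak_offset: curve mixes ion types or statistics",
         call. = FALSE)
  o <- order(curve$offset)
  curve$offset[o][which.max(curve$mean[o])]
}

#' @rdname average_curves
#' @param curves Data.frame from [average_curves()].
#' @param path File path.
#' @export
write_curves_tsv <- function(curves, path) {
  utils::write.table(curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
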