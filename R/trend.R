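# From per-peptide optimal offsets to deployable CE methods: absolute eV
# conversion, per-charge linear CE(m/z) trend fits, enzyme-class
# comparison, basic-residue grouping.

TRYPTIC_LIKE <- c("trypsin", "arg_c")
ALTERNATIVE <- c("glu_c", "asp_n", "chymotrypsin")

#' Enzyme class of a digestion enzyme
#'
#' Trypsin and Arg-C leave a basic residue (K/R) at the peptide C-terminus
#' and behave alike; Glu-C, Asp-N and chymotrypsin cleave at non-basic
#' residues and form the "alternative" class.
#'
#' @param enzyme Enzyme name (one of the [builtin_enzymes()] names).
#' @return `"TRYPTIC_LIKE"` or `"ALTERNATIVE"`.
#' @export
enzyme_class <- function(enzyme) {
  if (enzyme %in% TRYPTIC_LIKE) return("TRYPTIC_LIKE")
  if (enzyme %in% ALTERNATIVE) return("ALTERNATIVE")
  stop("unknown enzyme: ", enzyme, call. = FALSE)
}

#' Convert a fitted offset center to absolute collision energy
#'
#' Offsets are relative to the reference method's (unclamped) line; the
#' absolute optimum is reference + offset. Values below the instrument
#' floor can occur in reporting and are not clamped here.
#'
#' @param offset_center Fitted center in eV offset.
#' @param method The reference [ce_method()].
#' @param mz Precursor m/z.
#' @param charge Precursor charge.
#' @return Absolute CE in eV.
#' @export
to_absolute <- function(offset_center, method, mz, charge) {
  reference_ce_unclamped(method, mz, charge) + offset_center
}

#' Expand fit results into per-peak optimum points
#'
#' Each unimodal fit yields one point (`peak_role = "UNIMODAL"`); each
#' bimodal fit two (`"LOWER"`, `"HIGHER"`). Centers are converted to
#' absolute eV against the reference method; points whose absolute CE
#' falls below the instrument floor are flagged (`below_floor`), not
#' dropped.
#'
#' @param fits Data.frame from [fit_all_series()].
#' @param method Reference [ce_method()] the offsets were acquired against.
#' @param enzyme Enzyme name attached to every point.
#' @return Data.frame of optimum points: `peptide`, `charge`, `mz`,
#'   `enzyme`, `modality`, `peak_role`, `offset`, `ce`, `edge_flag`,
#'   `taller`, `below_floor`, `basicity`.
#' @export
optimum_points <- function(fits, method, enzyme) {
  # charges without a line in the reference method cannot be placed on the
  # absolute scale and are dropped here (they are also never used in trends)
  fits <- fits[as.character(fits$charge) %in% names(method$lines), ,
               drop = FALSE]
  expand <- function(role, center_col) {
    rows <- if (role == "UNIMODAL") fits$modality == "UNIMODAL"
            else fits$modality == "BIMODAL"
    f <- fits[rows, , drop = FALSE]
    if (nrow(f) == 0L) return(NULL)
    ce <- mapply(function(off, mz, z) to_absolute(off, method, mz, z),
                 f[[center_col]], f$mz, f$charge)
    data.frame(peptide = f$peptide, charge = f$charge, mz = f$mz,
               enzyme = enzyme, modality = f$modality, peak_role = role,
               offset = f[[center_col]], ce = ce, edge_flag = f$edge_flag,
               taller = f$taller, below_floor = ce < method$floor,
               stringsAsFactors = FALSE)
  }
  out <- rbind(expand("UNIMODAL", "center_lower"),
               expand("LOWER", "center_lower"),
               expand("HIGHER", "center_higher"))
  if (is.null(out))
    stop("optimum_points: no usable fits", call. = FALSE)
  out$basicity <- vapply(out$peptide, classify_basicity, character(1),
                         USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the optimum points that define an enzyme class's CE setting
#'
#' For the tryptic-like class the line fitted to the unimodal optima is
#' the deployed setting, so only `peak_role == "UNIMODAL"` points are
#' kept. For the alternative class the unimodal and lower bimodal optima
#' sit close together and are pooled (`"UNIMODAL"` and `"LOWER"`). Only
#' charges 2 and 3 enter trend fitting, and edge-flagged fits (center
#' censored at the grid boundary) are excluded.
#'
#' @param points Data.frame from [optimum_points()].
#' @param class `"TRYPTIC_LIKE"` or `"ALTERNATIVE"`; defaults to the class
#'   of the points' enzyme.
#' @return Subset of `points`.
#' @export
select_points <- function(points, class = NULL) {
  if (is.null(class)) {
    enz <- unique(points$enzyme)
    cls <- unique(vapply(enz, enzyme_class, character(1)))
    if (length(cls) != 1L)
      stop("select_points: points mix enzyme classes; pass 'class'",
           call. = FALSE)
    class <- cls
  }
  class <- match.arg(class, c("TRYPTIC_LIKE", "ALTERNATIVE"))
  roles <- if (class == "TRYPTIC_LIKE") "UNIMODAL" else c("UNIMODAL", "LOWER")
  points[points$peak_role %in% roles & points$charge %in% c(2L, 3L) &
           !points$edge_flag, , drop = FALSE]
}

#' Fit a linear optimal-CE(m/z) trend for one charge
#'
#' Ordinary least squares of absolute CE on m/z.
#'
#' @param points Optimum points for a single charge; needs >= 2 distinct
#'   m/z values.
#' @return Object of class `trend_line`: `slope`, `intercept`, `charge`,
#'   `label`, `n_points`, `residual_sd`, and standard errors `slope_se`,
#'   `intercept_se`.
#' @export
fit_line <- function(points) {
  if (nrow(points) < 2L || length(unique(points$mz)) < 2L)
    stop("fit_line: need >= 2 points with distinct m/z", call. = FALSE)
  charge <- unique(points$charge)
  if (length(charge) != 1L)
    stop("fit_line: points span multiple charges", call. = FALSE)
  fit <- stats::lm(ce ~ mz, data = points)
  co <- summary(fit)$coefficients
  structure(list(slope = unname(co["mz", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 slope_se = unname(co["mz", "Std. Error"]),
                 intercept_se = unname(co["(Intercept)", "Std. Error"]),
                 charge = charge,
                 label = paste(unique(points$enzyme), collapse = "+"),
                 n_points = nrow(points),
                 residual_sd = summary(fit)$sigma),
            class = "trend_line")
}

#' @export
print.trend_line <- function(x, ...) {
  cat(sprintf("<trend_line> %s z=%d: CE = %.4g * mz + %.4g (n=%d, sd %.2f)\n",
              x$label, x$charge, x$slope, x$intercept, x$n_points,
              x$residual_sd))
  invisible(x)
}

eval_line <- function(line, mz) line$slope * mz + line$intercept

#' Fit per-charge trend lines for an enzyme class
#'
#' @param points Selected points (see [select_points()]).
#' @param charges Charges to fit (default 2 and 3).
#' @return Named list of [fit_line()] results, one per charge.
#' @export
fit_trends <- function(points, charges = c(2L, 3L)) {
  out <- lapply(charges, function(z)
    fit_line(points[points$charge == z, , drop = FALSE]))
  names(out) <- as.character(charges)
  out
}

#' Tabulate trend lines
#'
#' @param trends Named list of [fit_line()] results.
#' @return Data.frame (charge, label, slope, intercept, n_points,
#'   residual_sd).
#' @export
trends_table <- function(trends) {
  do.call(rbind, lapply(trends, function(t)
    data.frame(charge = t$charge, label = t$label, slope = t$slope,
               intercept = t$intercept, slope_se = t$slope_se,
               intercept_se = t$intercept_se, n_points = t$n_points,
               residual_sd = t$residual_sd, stringsAsFactors = FALSE)))
}

#' Compare two enzyme-class trend lines
#'
#' Evaluates both lines over an even m/z grid and reports the mean
#' difference (tryptic minus alternative) in eV and as a percentage of the
#' tryptic setting.
#'
#' @param line_tryptic,line_alt [fit_line()] results for the same charge.
#' @param mz_range m/z window (default 300-1300 Th, the plotted domain of
#'   typical 2+/3+ peptides).
#' @param n_grid Number of evaluation points.
#' @return List with `mean_delta_ev` and `percent_lower`.
#' @export
compare_classes <- function(line_tryptic, line_alt,
                            mz_range = c(300, 1300), n_grid = 101L) {
  if (line_tryptic$charge != line_alt$charge)
    stop("compare_classes: lines are for different charges", call. = FALSE)
  mz <- seq(mz_range[1L], mz_range[2L], length.out = n_grid)
  ce_t <- eval_line(line_tryptic, mz)
  ce_a <- eval_line(line_alt, mz)
  if (any(ce_t <= 0))
    stop("compare_classes: tryptic CE non-positive on the grid",
         call. = FALSE)
  list(mean_delta_ev = mean(ce_t - ce_a),
       percent_lower = mean(100 * (ce_t - ce_a) / ce_t))
}

#' Fraction of bimodal peptides whose lower-energy peak is taller
#'
#' @param fits Data.frame from [fit_all_series()].
#' @return Fraction in [0, 1] over bimodal fits.
#' @export
fraction_lower_taller <- function(fits) {
  bi <- fits[fits$modality == "BIMODAL", , drop = FALSE]
  if (nrow(bi) == 0L)
    stop("fraction_lower_taller: no bimodal fits", call. = FALSE)
  mean(bi$taller == "LOWER")
}

#' Basic-residue grouping of a peptide
#'
#' `CTERM_BASIC` when the C-terminal residue is K or R (the tryptic /
#' Arg-C situation, where the basic residue stabilizes the y-ion series);
#' otherwise `INTERNAL_BASIC` when any residue is K, R or H; otherwise
#' `NO_BASIC`. Histidine counts as basic for the internal split but not
#' for the C-terminal label, which mirrors tryptic/Arg-C termini
#' specifically.
#'
#' @param sequence Peptide sequence.
#' @param cterm_basic,internal_basic Residue sets, overridable.
#' @return One of `"CTERM_BASIC"`, `"INTERNAL_BASIC"`, `"NO_BASIC"`.
#' @export
classify_basicity <- function(sequence, cterm_basic = c("K", "R"),
                              internal_basic = c("K", "R", "H")) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  if (chars[length(chars)] %in% cterm_basic) return("CTERM_BASIC")
  if (any(chars %in% internal_basic)) return("INTERNAL_BASIC")
  "NO_BASIC"
}

#' Assemble a deployable CE method from fitted trend lines
#'
#' @param trends Named list of [fit_line()] results for charges 2 and 3.
#' @param floor Instrument CE floor in eV.
#' @return A [ce_method()].
#' @export
build_method <- function(trends, floor = 5) {
  if (!all(c("2", "3") %in% names(trends)))
    stop("build_method: trends for charges 2 and 3 required", call. = FALSE)
  ce_method(lapply(trends, function(t)
    ce_line(t$charge, t$slope, t$intercept)), floor = floor)
}

#' NCE% range of a CE method over an m/z window
#'
#' Converts the method's clamped CE at the window ends into NCE% per
#' charge, giving the vendor-scale range a setting corresponds to.
#'
#' @param method A [ce_method()].
#' @param mz_range m/z window.
#' @param p [nce_params()].
#' @return Data.frame (charge, mz_lo, mz_hi, nce_lo, nce_hi).
#' @export
method_nce_range <- function(method, mz_range = c(300, 1300),
                             p = nce_params()) {
  do.call(rbind, lapply(method$lines, function(l) {
    nce <- ce_to_nce(reference_ce(method, mz_range, l$charge), mz_range,
                     l$charge, p)
    data.frame(charge = l$charge, mz_lo = mz_range[1L], mz_hi = mz_range[2L],
               nce_lo = min(nce), nce_hi = max(nce))
  }))
}
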