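# Linear CE(m/z) instrument methods, the CE-offset grid, the instrument
# floor, and eV <-> NCE% conversion.

#' Linear collision-energy line for one charge state
#'
#' Instruments ramp CID collision energy linearly with precursor m/z,
#' with a separate line per precursor charge: `CE(m/z) = slope * mz +
#' intercept`.
#'
#' @param charge Precursor charge state.
#' @param slope eV per Th.
#' @param intercept eV.
#' @return Object of class `ce_line`.
#' @export
ce_line <- function(charge, slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept), charge >= 1)
  structure(list(charge = as.integer(charge), slope = slope,
                 intercept = intercept),
            class = "ce_line")
}

#' Deployable collision-energy method
#'
#' A set of per-charge [ce_line()]s plus the instrument's lower CE limit.
#' The applied energy can never fall below `floor` (5 eV on the QTof
#' instrument the defaults describe).
#'
#' @param lines List of [ce_line()] objects; charges 2 and 3 must be present.
#' @param floor Instrument lower CE limit in eV (> 0).
#' @return Object of class `ce_method`.
#' @export
ce_method <- function(lines, floor = 5) {
  stopifnot(floor > 0)
  lines <- lapply(lines, function(l) {
    if (!inherits(l, "ce_line")) stop("all lines must be ce_line objects",
                                      call. = FALSE)
    l
  })
  charges <- vapply(lines, `[[`, integer(1), "charge")
  names(lines) <- as.character(charges)
  if (!all(c("2", "3") %in% names(lines)))
    stop("ce_method requires lines for charges 2 and 3", call. = FALSE)
  structure(list(lines = lines, floor = floor), class = "ce_method")
}

#' @export
print.ce_method <- function(x, ...) {
  cat(sprintf("<ce_method> floor %g eV\n", x$floor))
  for (l in x$lines)
    cat(sprintf("  z=%d: CE = %.5g * mz + %.5g\n", l$charge, l$slope,
                l$intercept))
  invisible(x)
}

get_line <- function(method, charge) {
  l <- method$lines[[as.character(charge)]]
  if (is.null(l))
    stop(sprintf("no CE line for charge %s in method", charge), call. = FALSE)
  l
}

#' Reference collision energy of a method
#'
#' Evaluates the method's line for the given charge at `mz` and clamps at
#' the instrument floor.
#'
#' @param method A [ce_method()].
#' @param mz Precursor m/z in Th (vectorised).
#' @param charge Precursor charge (must have a line in `method`).
#' @return CE in eV, never below `method$floor`.
#' @export
reference_ce <- function(method, mz, charge) {
  l <- get_line(method, charge)
  pmax(method$floor, l$slope * mz + l$intercept)
}

reference_ce_unclamped <- function(method, mz, charge) {
  l <- get_line(method, charge)
  l$slope * mz + l$intercept
}

#' Collision-energy offset grid
#'
#' The arithmetic sequence of CE offsets (eV, relative to the reference
#' method) at which the energy-dependent series is acquired. The default
#' experiment spans -20 to +20 eV in 2 eV steps: 21 runs.
#'
#' @param lo,hi Range ends in eV (`lo <= hi`).
#' @param step Step in eV (> 0); `(hi - lo)` must be a multiple of `step`.
#' @return Numeric vector `lo, lo + step, ..., hi`.
#' @examples
#' length(offset_grid()) # 21
#' @export
offset_grid <- function(lo = -20, hi = 20, step = 2) {
  stopifnot(lo <= hi, step > 0)
  n <- (hi - lo) / step
  if (abs(n - round(n)) > 1e-9)
    stop("offset_grid: (hi - lo) is not a multiple of step", call. = FALSE)
  lo + step * (0:round(n))
}

#' Applied collision energy at an offset
#'
#' The energy actually applied when the whole method is shifted by
#' `offset` eV: the unclamped reference plus the offset, clamped at the
#' floor.
#'
#' @inheritParams reference_ce
#' @param offset CE offset in eV (vectorised).
#' @return CE in eV, never below the floor.
#' @export
applied_ce <- function(method, mz, charge, offset) {
  pmax(method$floor, reference_ce_unclamped(method, mz, charge) + offset)
}

#' Normalized-collision-energy conversion parameters
#'
#' On Orbitrap-style instruments the collision energy is expressed as NCE%,
#' a dimensionless setting from which the actual energy is derived by
#' scaling with precursor m/z (relative to a reference m/z) and a
#' charge-dependent factor: `CE = NCE * (mz / reference_mz) *
#' charge_factor[z]`. The vendor constants are instrument-specific, so they
#' are plain configuration here; the defaults are the commonly cited ones.
#'
#' @param reference_mz Reference m/z in Th (default 500).
#' @param charge_factor Named numeric of per-charge factors; charges above
#'   the largest named charge reuse the last factor.
#' @return Object of class `nce_params`.
#' @export
nce_params <- function(reference_mz = 500,
                       charge_factor = c(`1` = 1.0, `2` = 0.9,
                                         `3` = 0.85, `4` = 0.8)) {
  stopifnot(reference_mz > 0, all(charge_factor > 0))
  structure(list(reference_mz = reference_mz, charge_factor = charge_factor),
            class = "nce_params")
}

nce_factor <- function(p, charge) {
  key <- as.character(charge)
  known <- as.integer(names(p$charge_factor))
  if (key %in% names(p$charge_factor)) return(p$charge_factor[[key]])
  if (charge > max(known)) return(p$charge_factor[[as.character(max(known))]])
  stop(sprintf("no NCE charge factor for charge %s", charge), call. = FALSE)
}

#' Convert between absolute collision energy (eV) and NCE%
#'
#' The two functions are exact inverses:
#' `CE = NCE * (mz / reference_mz) * charge_factor[z]`.
#'
#' @param ce Collision energy in eV.
#' @param nce Normalized collision energy in %.
#' @param mz Precursor m/z in Th.
#' @param charge Precursor charge.
#' @param p An [nce_params()].
#' @return `ce_to_nce()`: NCE%; `nce_to_ce()`: eV.
#' @export
ce_to_nce <- function(ce, mz, charge, p = nce_params()) {
  stopifnot(all(mz > 0))
  ce / ((mz / p$reference_mz) * nce_factor(p, charge))
}

#' @rdname ce_to_nce
#' @export
nce_to_ce <- function(nce, mz, charge, p = nce_params()) {
  stopifnot(all(mz > 0))
  nce * (mz / p$reference_mz) * nce_factor(p, charge)
}

#' Read / write a CE method as a YAML config block
#'
#' The on-disk format is a small mapping: `floor` plus a `lines` list of
#' `{charge, slope, intercept}` entries.
#'
#' @param path File path.
#' @param method A [ce_method()].
#' @return `read_ce_method()` returns a [ce_method()].
#' @export
read_ce_method <- function(path) {
  cfg <- yaml::read_yaml(path)
  lines <- lapply(cfg$lines, function(l)
    ce_line(l$charge, l$slope, l$intercept))
  ce_method(lines, floor = cfg$floor)
}

#' @rdname read_ce_method
#' @export
write_ce_method <- function(method, path) {
  cfg <- list(
    floor = method$floor,
    lines = unname(lapply(method$lines, function(l)
      list(charge = l$charge, slope = l$slope, intercept = l$intercept)))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Default reference CE method
#'
#' The tryptic-optimized linear CE(m/z) setting used as the zero-offset
#' reference by the synthetic experiment generator, with the 5 eV
#' instrument floor. Slopes and intercepts are the generator's model of a
#' QTof tryptic method; real analyses should load their own method with
#' [read_ce_method()].
#'
#' @return A [ce_method()].
#' @export
default_reference_method <- function() {
  ce_method(list(ce_line(2L, 0.050, 10), ce_line(3L, 0.044, 15)), floor = 5)
}
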