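# Experimental-side epitope handling: mono-exponential build-up fitting
# (STD(t) = STDmax (1 - exp(-ksat t)), STD0 = STDmax * ksat) and NOE
# R-factor scoring of calculated vs experimental relative epitopes.

#' Fit a mono-exponential STD build-up curve
#'
#' Nonlinear least squares of `STD(t) = STDmax * (1 - exp(-ksat * t))`;
#' the initial slope is the product `STD0 = STDmax * ksat`, the epitope
#' quantity least biased by relaxation artifacts. Initialization:
#' `STDmax0 = max(STD)`, `ksat0 = 1 / t_halfmax`; both parameters are
#' bounded below by 0.
#'
#' @param t_sat Saturation times (s), strictly increasing, length >= 3.
#' @param std STD factors `(I0 - Isat)/I0` at each time (sanity band
#'   0 to 1.5).
#' @return List: `stdmax`, `ksat` (s^-1), `std0` (s^-1), `resid_norm`,
#'   `fit` (the underlying `nls` object).
#' @export
fit_buildup <- function(t_sat, std) {
  if (length(t_sat) < 3L) stop("build-up fitting needs >= 3 points")
  if (length(std) != length(t_sat)) stop("t_sat and std lengths differ")
  if (is.unsorted(t_sat, strictly = TRUE)) {
    stop("t_sat must be strictly increasing")
  }
  if (any(std < -0.05) || any(std > 1.5)) {
    stop("STD factors outside the [0, 1.5] sanity band; are these ",
         "(I0 - Isat)/I0 values?")
  }
  stdmax0 <- max(std)
  if (stdmax0 <= 0) stop("all STD factors are <= 0; nothing to fit")
  half <- which(std >= stdmax0 / 2)[1]
  ksat0 <- if (!is.na(half) && t_sat[half] > 0) 1 / t_sat[half] else 1
  dat <- data.frame(t_sat = t_sat, std = std)
  fit <- tryCatch(
    stats::nls(std ~ stdmax * (1 - exp(-ksat * t_sat)), data = dat,
               start = list(stdmax = stdmax0, ksat = ksat0),
               lower = c(stdmax = 1e-12, ksat = 1e-12),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) {
      stop("build-up fit did not converge (start STDmax=", signif(stdmax0, 4),
           ", ksat=", signif(ksat0, 4), "): ", conditionMessage(e))
    }
  )
  cf <- stats::coef(fit)
  list(stdmax = unname(cf["stdmax"]), ksat = unname(cf["ksat"]),
       std0 = unname(cf["stdmax"] * cf["ksat"]),
       resid_norm = sqrt(sum(stats::resid(fit)^2)), fit = fit)
}

#' Construct a relative epitope
#'
#' Entries are renormalized so the largest equals exactly 100%.
#'
#' @param keys Proton keys (character, unique).
#' @param values Non-negative STD0 values (any common scale).
#' @param provenance `"experimental"` or `"calculated"`.
#' @return An `epitope` data.frame with columns `epitope_key`, `rel`.
#' @export
epitope <- function(keys, values, provenance = c("experimental", "calculated")) {
  provenance <- match.arg(provenance)
  keys <- as.character(keys)
  if (anyDuplicated(keys)) stop("duplicate epitope keys: ",
                                paste(keys[duplicated(keys)], collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("epitope values must be finite and >= 0")
  }
  if (max(values) <= 0) stop("all epitope values are zero")
  out <- data.frame(epitope_key = keys, rel = 100 * values / max(values),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("epitope", "data.frame")
  out
}

#' @export
as_epitope <- function(x, ...) UseMethod("as_epitope")

#' @export
as_epitope.calculated_epitope <- function(x, ...) {
  keep <- !is.na(x$epitope_key)
  epitope(x$epitope_key[keep], pmax(x$std0_abs[keep], 0), "calculated")
}

#' @export
as_epitope.epitope <- function(x, ...) x

#' NOE R-factor between experimental and calculated epitopes
#'
#' `R = sqrt( sum_k W_k (STD0exp_k - STD0cal_k)^2 / sum_k W_k (STD0exp_k)^2 )`
#' over the keys shared by both epitopes, on the relative (%) scale, with
#' unit weights by default. Values below ~0.3 indicate good agreement.
#'
#' @param exp_epitope,cal_epitope [epitope()] objects (or a
#'   `calculated_epitope`, converted automatically).
#' @param weights Optional named numeric vector of per-key weights W_k
#'   (default all 1); keys absent from the overlap are ignored.
#' @return A `score_result` list: `r_factor`, `n_matched`, `pairs`
#'   (data.frame key/exp/cal/weight), `unmatched_exp`, `unmatched_cal`.
#' @export
noe_r_factor <- function(exp_epitope, cal_epitope, weights = NULL) {
  exp_epitope <- as_epitope(exp_epitope)
  cal_epitope <- as_epitope(cal_epitope)
  shared <- intersect(exp_epitope$epitope_key, cal_epitope$epitope_key)
  if (!length(shared)) {
    stop("no shared proton keys between experimental and calculated epitopes")
  }
  ev <- exp_epitope$rel[match(shared, exp_epitope$epitope_key)]
  cv <- cal_epitope$rel[match(shared, cal_epitope$epitope_key)]
  w <- rep(1, length(shared))
  if (!is.null(weights)) {
    hit <- match(shared, names(weights))
    w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
    if (any(w < 0)) stop("weights must be >= 0")
  }
  denom <- sum(w * ev^2)
  if (denom <= 0) stop("experimental epitope is all zero over shared keys")
  r <- sqrt(sum(w * (ev - cv)^2) / denom)
  if (length(shared) < 4L) {
    warning(sprintf(
      "only %d matched proton(s): R-factor is prone to false positives/negatives with few epitope points",
      length(shared)))
  }
  structure(
    list(r_factor = r, n_matched = length(shared),
         pairs = data.frame(epitope_key = shared, exp = ev, cal = cv,
                            weight = w, stringsAsFactors = FALSE),
         unmatched_exp = setdiff(exp_epitope$epitope_key, shared),
         unmatched_cal = setdiff(cal_epitope$epitope_key, shared)),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> NOE R-factor = %.3f over %d protons (%s)\n",
              x$r_factor, x$n_matched, classify_fit(x)))
  invisible(x)
}

#' Classify a score as good or poor agreement
#'
#' Rule of thumb: an NOE R-factor strictly below 0.3 indicates good
#' agreement between calculated and experimental STD0 values.
#'
#' @param score A `score_result` (or bare numeric R-factor).
#' @param threshold Decision threshold (default 0.3, strict `<`).
#' @return `"good"` or `"poor"`.
#' @export
classify_fit <- function(score, threshold = 0.3) {
  r <- if (inherits(score, "score_result")) score$r_factor else score
  stopifnot(is.numeric(r), r >= 0)
  if (r < threshold) "good" else "poor"
}

#' Read an experimental epitope file
#'
#' Two layouts of whitespace/comma-delimited text (with optional `#`
#' comments and a header line):
#' wide, `proton_key value` (relative STD0, percent); or long,
#' `proton_key t_sat std` build-up points, fitted per key with
#' [fit_buildup()] and converted to relative STD0.
#'
#' @param path File path.
#' @return An experimental [epitope()].
#' @export
read_epitope <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(gsub(",", " ", ln, fixed = TRUE))
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("epitope file is empty: ", path)
  fields <- strsplit(ln, "[[:space:]]+")
  # drop a header line if its second field is non-numeric
  if (is.na(suppressWarnings(as.numeric(fields[[1]][2])))) {
    fields <- fields[-1]
  }
  if (!length(fields)) stop("epitope file has no data rows: ", path)
  nf <- unique(lengths(fields))
  if (length(nf) != 1L || !nf %in% c(2L, 3L)) {
    stop("epitope file must have 2 (key value) or 3 (key t_sat std) ",
         "columns throughout: ", path)
  }
  raw <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  if (nf == 3L) {
    t_sat <- as.numeric(raw[[2]]); std <- as.numeric(raw[[3]])
    if (anyNA(t_sat) || anyNA(std)) stop("non-numeric build-up values in ", path)
    keys <- as.character(raw[[1]])
    std0 <- vapply(unique(keys), function(k) {
      sel <- keys == k
      ord <- order(t_sat[sel])
      fit_buildup(t_sat[sel][ord], std[sel][ord])$std0
    }, numeric(1))
    epitope(unique(keys), std0, "experimental")
  } else {
    vals <- as.numeric(raw[[2]])
    if (anyNA(vals)) stop("non-numeric epitope values in ", path)
    epitope(as.character(raw[[1]]), vals, "experimental")
  }
}

#' Write an epitope (or calculated epitope) as delimited text
#'
#' @param x An `epitope` or `calculated_epitope`.
#' @param path Output path.
#' @export
write_epitope <- function(x, path) {
  if (inherits(x, "calculated_epitope")) {
    df <- data.frame(proton_key = x$epitope_key, std0_abs = x$std0_abs,
                     rel_percent = round(x$rel, 1))
  } else {
    df <- data.frame(proton_key = x$epitope_key, rel_percent = round(x$rel, 1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
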