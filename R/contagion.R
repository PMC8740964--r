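#' Contagion rule specification
#'
#' Selects the agent-level belief-update rule used during cascades and houses
#' its parameters. Five variants are supported:
#'
#' * `"simple"`: disease-style adoption with a fixed probability `p` per
#'   exposure, independent of both beliefs.
#' * `"proportional"`: deterministic adoption when the fraction of the
#'   receiver's neighbors already holding the candidate level reaches
#'   `ratio_alpha` (complex contagion).
#' * `"linear"`: inverse-linear cognitive rule,
#'   `beta(d) = 1 / (lin_gamma + lin_alpha * d)` (clamped to 1), where
#'   `d = |holder - incoming|` is the belief distance.
#' * `"threshold"`: bounded-confidence rule, `beta(d) = 1` iff
#'   `d <= thr_gamma`.
#' * `"sigmoid"`: logistic cognitive rule,
#'   `beta(d) = 1 / (1 + exp(sig_alpha * (d - sig_gamma)))`. The "stubborn"
#'   parameterization `sig_alpha = 4`, `sig_gamma = 2` is the defensive
#'   cognitive contagion (DCC) rule: near beliefs are adopted almost surely,
#'   distance 2 is a coin flip, and distance >= 3 collapses toward zero,
#'   combining dissonance (rejection of distant beliefs) with exposure
#'   (repeated near-beliefs eventually adopted).
#'
#' `contagion_preset()` returns named parameterizations studied with the
#' model: `"simple"`, `"proportional"`, `"dcc"` (alias
#' `"sigmoid-stubborn"`), `"sigmoid-normal"`, `"sigmoid-gullible"`,
#' `"linear-gullible"`, `"linear-normal"`, `"linear-stubborn"`,
#' `"threshold-gullible"`, `"threshold-normal"`, `"threshold-stubborn"`.
#'
#' @param variant One of `"simple"`, `"proportional"`, `"linear"`,
#'   `"threshold"`, `"sigmoid"`.
#' @param p Simple-contagion spread chance (default 0.15).
#' @param ratio_alpha Proportional-threshold neighbor ratio (default 0.35).
#' @param lin_gamma,lin_alpha Inverse-linear bias and slope.
#' @param thr_gamma Threshold distance bound.
#' @param sig_alpha,sig_gamma Sigmoid steepness and shift (DCC: 4 and 2).
#'
#' @return An object of class `contagion_spec`.
#' @examples
#' contagion_preset("dcc")
#' contagion_spec("sigmoid", sig_alpha = 2, sig_gamma = 3)
#' @export
contagion_spec <- function(variant = c("simple", "proportional", "linear",
                                       "threshold", "sigmoid"),
                           p = 0.15, ratio_alpha = 0.35,
                           lin_gamma = 1, lin_alpha = 1,
                           thr_gamma = 1,
                           sig_alpha = 4, sig_gamma = 2) {
  variant <- match.arg(variant)
  if (p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  if (ratio_alpha < 0 || ratio_alpha > 1) abort("`ratio_alpha` must lie in [0, 1].")
  if (variant == "linear" && lin_gamma <= 0 && lin_alpha <= 0) {
    abort("linear rule needs a positive denominator: `lin_gamma + lin_alpha * d > 0`.")
  }
  if (variant == "linear" && lin_gamma == 0) {
    abort("`lin_gamma` must be > 0 (zero denominator at distance 0).")
  }
  if (thr_gamma < 0) abort("`thr_gamma` must be >= 0.")
  structure(
    list(variant = variant, p = p, ratio_alpha = ratio_alpha,
         lin_gamma = lin_gamma, lin_alpha = lin_alpha,
         thr_gamma = thr_gamma, sig_alpha = sig_alpha, sig_gamma = sig_gamma),
    class = "contagion_spec"
  )
}

#' @rdname contagion_spec
#' @param name Preset name (see Details).
#' @export
contagion_preset <- function(name) {
  presets <- list(
    "simple"             = list(variant = "simple"),
    "proportional"       = list(variant = "proportional"),
    "dcc"                = list(variant = "sigmoid", sig_alpha = 4, sig_gamma = 2),
    "sigmoid-stubborn"   = list(variant = "sigmoid", sig_alpha = 4, sig_gamma = 2),
    "sigmoid-normal"     = list(variant = "sigmoid", sig_alpha = 2, sig_gamma = 3),
    "sigmoid-gullible"   = list(variant = "sigmoid", sig_alpha = 1, sig_gamma = 7),
    "linear-gullible"    = list(variant = "linear", lin_gamma = 1, lin_alpha = 0),
    "linear-normal"      = list(variant = "linear", lin_gamma = 1, lin_alpha = 1),
    "linear-stubborn"    = list(variant = "linear", lin_gamma = 10, lin_alpha = 20),
    "threshold-gullible" = list(variant = "threshold", thr_gamma = 6),
    "threshold-normal"   = list(variant = "threshold", thr_gamma = 3),
    "threshold-stubborn" = list(variant = "threshold", thr_gamma = 1)
  )
  if (!name %in% names(presets)) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(names(presets), collapse = ", ")))
  }
  do.call(contagion_spec, presets[[name]])
}

#' @export
print.contagion_spec <- function(x, ...) {
  pars <- switch(x$variant,
    simple = sprintf("p = %g", x$p),
    proportional = sprintf("alpha = %g", x$ratio_alpha),
    linear = sprintf("gamma = %g, alpha = %g", x$lin_gamma, x$lin_alpha),
    threshold = sprintf("gamma = %g", x$thr_gamma),
    sigmoid = sprintf("alpha = %g, gamma = %g", x$sig_alpha, x$sig_gamma))
  cat("<contagion_spec> ", x$variant, " (", pars, ")\n", sep = "")
  invisible(x)
}

# Distance-based beta for the cognitive variants; vectorized over `distance`.
beta_at_distance <- function(spec, distance) {
  switch(spec$variant,
    linear = pmin(1, 1 / (spec$lin_gamma + spec$lin_alpha * distance)),
    threshold = as.numeric(distance <= spec$thr_gamma),
    sigmoid = 1 / (1 + exp(pmin(700, spec$sig_alpha * (distance - spec$sig_gamma)))),
    abort(sprintf("variant '%s' has no pairwise beta function.", spec$variant))
  )
}

#' Adoption probability for one exposure
#'
#' Computes the probability that an agent holding belief `holder` adopts an
#' incoming belief `incoming` upon a single exposure, under the rule in
#' `spec`. For the `"simple"` variant the probability is the constant `p`;
#' for the cognitive variants it is the variant's beta function of the belief
#' distance `|holder - incoming|`; for the `"proportional"` variant it is 1
#' or 0 according to whether the fraction of `neighbor_beliefs` equal to
#' `incoming` reaches `ratio_alpha` (an empty neighborhood yields 0: an
#' isolated agent cannot be peer-pressured).
#'
#' Positive and negative belief changes are weighted equally: only the
#' absolute distance enters.
#'
#' @param spec A [contagion_spec()].
#' @param holder,incoming Belief levels (vectorized, recycled).
#' @param neighbor_beliefs Integer vector of the receiving agent's neighbors'
#'   current beliefs (proportional variant only).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' adoption_probability(contagion_preset("dcc"), 6, 5)
#' adoption_probability(contagion_preset("simple"), 0, 6)
#' @export
adoption_probability <- function(spec, holder, incoming,
                                 neighbor_beliefs = NULL) {
  stopifnot(inherits(spec, "contagion_spec"))
  if (spec$variant == "simple") {
    return(rep(spec$p, max(length(holder), length(incoming))))
  }
  if (spec$variant == "proportional") {
    if (length(incoming) != 1) {
      abort("proportional rule takes a single candidate level.")
    }
    if (is.null(neighbor_beliefs) || !length(neighbor_beliefs)) {
      return(0)
    }
    frac <- mean(neighbor_beliefs == incoming)
    return(as.numeric(frac >= spec$ratio_alpha))
  }
  beta_at_distance(spec, abs(holder - incoming))
}

#' One Bernoulli adoption trial
#'
#' Dispatches to the variant's adoption probability and draws one Bernoulli
#' outcome from R's current random stream. `TRUE` means the caller should set
#' the holder's belief to `incoming` — a discrete jump to the incoming level,
#' with no averaging.
#'
#' @inheritParams adoption_probability
#' @return Logical scalar.
#' @export
adoption_trial <- function(spec, holder, incoming, neighbor_beliefs = NULL) {
  pr <- adoption_probability(spec, holder, incoming, neighbor_beliefs)
  stopifnot(length(pr) == 1)
  runif(1) < pr
}

#' Pairwise adoption-probability matrix
#'
#' The full holder-by-incoming matrix of single-exposure adoption
#' probabilities for a distance-based cognitive rule. Under the DCC defaults
#' the matrix is the model's signature: near-certain adoption within distance
#' 1, 0.5 at distance 2, and a collapse below 0.02 beyond.
#'
#' @param space A [belief_space()].
#' @param spec A cognitive [contagion_spec()] (linear, threshold or sigmoid).
#' @return A numeric `R x R` matrix, symmetric and constant along diagonals,
#'   with belief levels as dimnames.
#' @examples
#' round(dcc_probability_matrix(belief_space(), contagion_preset("dcc")), 3)
#' @export
dcc_probability_matrix <- function(space = belief_space(),
                                   spec = contagion_preset("dcc")) {
  lv <- space$levels
  d <- abs(outer(lv, lv, "-"))
  m <- matrix(beta_at_distance(spec, d), space$resolution, space$resolution,
              dimnames = list(holder = lv, incoming = lv))
  m
}

#' Rescale distance parameters to another belief resolution
#'
#' The cognitive rules are calibrated on the 7-level scale (maximum distance
#' 6). To run the model at another resolution `R` while preserving the
#' probability profile over *relative* belief distance, the distance-typed
#' parameters are multiplied by `(R - 1) / 6`: `sig_gamma` and `thr_gamma`
#' scale up, and the linear slope `lin_alpha` scales down (so that
#' `lin_alpha * d` is preserved at equivalent relative distances).
#'
#' @param spec A [contagion_spec()].
#' @param space The target [belief_space()].
#' @return A rescaled `contagion_spec`.
#' @examples
#' scale_spec_for_resolution(contagion_preset("dcc"), belief_space(13))
#' @export
scale_spec_for_resolution <- function(spec, space) {
  s <- (space$resolution - 1) / 6
  spec$sig_gamma <- spec$sig_gamma * s
  spec$thr_gamma <- spec$thr_gamma * s
  spec$lin_alpha <- spec$lin_alpha / s
  spec
}

#' Export an adoption-probability matrix as CSV
#'
#' Writes the matrix with a `holder` column and one column per incoming
#' belief level.
#'
#' @param m Matrix from [dcc_probability_matrix()].
#' @param path File path.
#' @export
write_probability_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- colnames(m)
  df <- dplyr::bind_cols(tibble::tibble(holder = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(m)
}

#' Heatmap of an adoption-probability matrix
#'
#' @param m Matrix from [dcc_probability_matrix()].
#' @return A ggplot object.
#' @export
plot_probability_matrix <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("holder", "incoming", "probability")
  ggplot2::ggplot(df, ggplot2::aes(.data$incoming, .data$holder,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$probability)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "incoming belief", y = "holder belief",
                  fill = "P(adopt)") +
    ggplot2::theme_minimal()
}
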