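#' Model identifiers and response conventions
#'
#' Four likelihood variants are implemented:
#' \describe{
#'   \item{SWo / SSo}{dual-rate Q-learning with separate gain/loss learning
#'     rates and an inverse *gain* softmax (Q-values divided by `beta`,
#'     `beta >= 0`); SWo and SSo share the likelihood and differ only in
#'     their hierarchical priors (wide vs. narrow).}
#'   \item{ES}{dual-rate model extended by a forgetting rate `phi` (all six
#'     Q-values decay toward 0 each trial), an initial bias `q0` (the
#'     first-chosen stimulus of a pair starts at `q0`), and irreducible
#'     noise `xi`; inverse-*temperature* softmax (`Q * beta`, `beta` in
#'     `[0, 20]`).}
#'   \item{RLfCK}{single learning rate plus forgetting and a choice kernel
#'     tracking recent choices, weighted by a choice inverse temperature
#'     `tau` in `[-5, 5]`.}
#' }
#' The SWo-structured model can also be run under the inverse-temperature
#' convention (`response_convention = "inverse_temperature"`, `beta` in
#' `[0, 20]`), mirroring common hierarchical-modelling toolkits.
#'
#' @name model_ids
NULL

MODEL_IDS <- c("SWo", "SSo", "ES", "RLfCK")

# integer family code passed to the C++ kernels
model_family <- function(model_id, response_convention = NULL) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (model_id %in% c("SWo", "SSo")) {
    conv <- response_convention %||% "inverse_gain"
    conv <- match.arg(conv, c("inverse_gain", "inverse_temperature"))
    if (conv == "inverse_gain") 1L else 2L
  } else if (model_id == "ES") 3L else 4L
}

#' Parameter specification of a model variant
#'
#' Gives, for each parameter, its name, its constrained bounds, and the
#' bijection linking the unconstrained sampling scale to the constrained
#' scale: `logit` for `[0, 1]` parameters, `log` for positive parameters
#' (the inverse gain), and a scaled logit `lo + (hi - lo) * logistic(x)` for
#' other bounded ranges.
#'
#' @param model_id one of `"SWo"`, `"SSo"`, `"ES"`, `"RLfCK"`.
#' @param response_convention for SWo/SSo: `"inverse_gain"` (default;
#'   `beta` on a log scale) or `"inverse_temperature"` (`beta` in `[0, 20]`).
#' @return data.frame with columns `name`, `transform`, `lo`, `hi`.
#' @export
param_spec <- function(model_id, response_convention = NULL) {
  family <- model_family(model_id, response_convention)
  spec <- switch(family,
    data.frame(name = c("a_gain", "a_loss", "beta"),
               transform = c("logit", "logit", "log"),
               lo = c(0, 0, 0), hi = c(1, 1, Inf)),
    data.frame(name = c("a_gain", "a_loss", "beta"),
               transform = c("logit", "logit", "scaled_logit"),
               lo = c(0, 0, 0), hi = c(1, 1, 20)),
    data.frame(name = c("a_gain", "a_loss", "beta", "phi", "xi", "q0"),
               transform = c("logit", "logit", "scaled_logit", "logit", "logit", "logit"),
               lo = c(0, 0, 0, 0, 0, 0), hi = c(1, 1, 20, 1, 1, 1)),
    data.frame(name = c("alpha", "phi", "beta", "a_ck", "tau"),
               transform = c("logit", "logit", "scaled_logit", "logit", "scaled_logit"),
               lo = c(0, 0, 0, 0, -5), hi = c(1, 1, 20, 1, 5))
  )
  attr(spec, "family") <- family
  spec
}

#' Map unconstrained parameters to the constrained scale
#'
#' @param x numeric vector (or matrix with one column per parameter) on the
#'   unconstrained scale, ordered as in `spec`.
#' @param spec a [param_spec()] data.frame.
#' @return constrained values with the same shape as `x`.
#' @export
constrain_pars <- function(x, spec) {
  f <- function(xi, tr, lo, hi) {
    switch(tr,
      logit = plogis(xi),
      log = exp(xi),
      scaled_logit = lo + (hi - lo) * plogis(xi)
    )
  }
  if (is.matrix(x)) {
    out <- x
    for (k in seq_len(ncol(x))) {
      out[, k] <- f(x[, k], spec$transform[k], spec$lo[k], spec$hi[k])
    }
    colnames(out) <- spec$name
    out
  } else {
    out <- mapply(f, x, spec$transform, spec$lo, spec$hi)
    names(out) <- spec$name
    out
  }
}

#' Map constrained parameters to the unconstrained scale
#'
#' Inverse of [constrain_pars()].
#'
#' @param p constrained values (vector or matrix), ordered as in `spec`.
#' @param spec a [param_spec()] data.frame.
#' @return unconstrained values with the same shape as `p`.
#' @export
unconstrain_pars <- function(p, spec) {
  f <- function(pi, tr, lo, hi) {
    switch(tr,
      logit = qlogis(pi),
      log = log(pi),
      scaled_logit = qlogis((pi - lo) / (hi - lo))
    )
  }
  if (is.matrix(p)) {
    out <- p
    for (k in seq_len(ncol(p))) {
      out[, k] <- f(p[, k], spec$transform[k], spec$lo[k], spec$hi[k])
    }
    colnames(out) <- spec$name
    out
  } else {
    out <- mapply(f, p, spec$transform, spec$lo, spec$hi)
    names(out) <- spec$name
    out
  }
}

# order a named parameter vector/list as the spec expects; validate bounds
canonical_params <- function(params, spec, check = TRUE) {
  params <- unlist(params)
  if (is.null(names(params))) {
    if (length(params) != nrow(spec)) {
      stop("expected ", nrow(spec), " parameters (", paste(spec$name, collapse = ", "), ")")
    }
    names(params) <- spec$name
  }
  missing <- setdiff(spec$name, names(params))
  if (length(missing)) stop("missing parameter(s): ", paste(missing, collapse = ", "))
  params <- params[spec$name]
  if (check) {
    bad <- is.na(params) | params < spec$lo | params > spec$hi
    if (any(bad)) {
      stop("parameter(s) out of bounds: ", paste(spec$name[bad], collapse = ", "))
    }
  }
  params
}

#' Serialize model parameters to JSON
#'
#' @param params named constrained parameter vector or list.
#' @param model_id model identifier (stored in the document).
#' @param response_convention see [param_spec()].
#' @param path optional output file.
#' @return JSON string (invisibly if written to `path`).
#' @export
params_to_json <- function(params, model_id, response_convention = NULL, path = NULL) {
  spec <- param_spec(model_id, response_convention)
  params <- canonical_params(params, spec)
  doc <- c(list(model_id = model_id), as.list(params))
  if (!is.null(response_convention)) doc$response_convention <- response_convention
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read model parameters from JSON
#'
#' @param path file path or JSON string from [params_to_json()].
#' @return list with `model_id`, `response_convention` (possibly `NULL`) and
#'   the named constrained parameter vector `params`.
#' @export
params_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$model_id)) stop("model_id is a required field")
  model_id <- match.arg(doc$model_id, MODEL_IDS)
  conv <- doc$response_convention
  spec <- param_spec(model_id, conv)
  params <- canonical_params(doc[spec$name], spec)
  list(model_id = model_id, response_convention = conv, params = params)
}

#' Default generating parameters of a model variant
#'
#' Mid-range values used as simulation defaults: moderate gain learning,
#' floored loss learning, fairly informative choices.
#'
#' @param model_id model identifier.
#' @param response_convention see [param_spec()].
#' @return named constrained parameter vector.
#' @export
default_params <- function(model_id, response_convention = NULL) {
  family <- model_family(model_id, response_convention)
  switch(family,
    c(a_gain = 0.35, a_loss = 0.12, beta = 0.15),
    c(a_gain = 0.35, a_loss = 0.12, beta = 6),
    c(a_gain = 0.35, a_loss = 0.12, beta = 6, phi = 0.1, xi = 0.05, q0 = 0.3),
    c(alpha = 0.3, phi = 0.1, beta = 6, a_ck = 0.3, tau = 1)
  )
}
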