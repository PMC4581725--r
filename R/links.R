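#' Link functions relating penetrance to the linear predictor
#'
#' A link specification is an invertible, strictly monotone map `g` from the
#' penetrance scale (0, 1) to the linear-predictor scale. The five links
#' supported are the ones commonly used in case-control interaction
#' modelling:
#'
#' * `identity` — additive penetrance, `g(p) = p`
#' * `log` — multiplicative penetrance, `g(p) = log(p)`
#' * `log_complement` — genetic heterogeneity, `g(p) = log(1 - p)` (decreasing)
#' * `odds` — additive odds, `g(p) = p / (1 - p)`
#' * `logit` — multiplicative odds, `g(p) = log(p / (1 - p))`
#'
#' The inverse `g_inverse` clamps its result into `[1e-10, 1 - 1e-10]`: for
#' the non-logit links the natural inverse can leave (0, 1), and all model
#' fitting treats that box constraint as part of the model. `mu_eta` is the
#' derivative of the inverse, set to 0 where the clamp is active so that
#' gradients remain consistent with the constrained fit.
#'
#' @param name Link name, one of `"identity"`, `"log"`, `"log_complement"`,
#'   `"odds"`, `"logit"`.
#' @return An object of class `link_spec`: a list with elements `name`, `g`,
#'   `g_inverse`, `mu_eta` and `increasing`.
#' @examples
#' lk <- link_spec("odds")
#' p <- c(0.01, 0.5, 0.99)
#' lk$g_inverse(lk$g(p))
#' @export
link_spec <- function(name = c("identity", "log", "log_complement", "odds", "logit")) {
  name <- match.arg(name)
  eps <- 1e-10
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  spec <- switch(name,
    identity = list(
      g = function(p) p,
      g_inverse = function(eta) clamp(eta),
      mu_eta = function(eta) as.numeric(eta > eps & eta < 1 - eps),
      increasing = TRUE
    ),
    log = list(
      g = function(p) log(p),
      g_inverse = function(eta) clamp(exp(eta)),
      mu_eta = function(eta) {
        p <- exp(eta)
        ifelse(p > eps & p < 1 - eps, p, 0)
      },
      increasing = TRUE
    ),
    log_complement = list(
      g = function(p) log(1 - p),
      g_inverse = function(eta) clamp(1 - exp(eta)),
      mu_eta = function(eta) {
        p <- 1 - exp(eta)
        ifelse(p > eps & p < 1 - eps, -(1 - p), 0)
      },
      increasing = FALSE
    ),
    odds = list(
      g = function(p) p / (1 - p),
      g_inverse = function(eta) clamp(eta / (1 + pmax(eta, 0))),
      mu_eta = function(eta) {
        ok <- eta > eps / (1 - eps) & is.finite(eta)
        ifelse(ok, 1 / (1 + eta)^2, 0)
      },
      increasing = TRUE
    ),
    logit = list(
      g = function(p) qlogis(p),
      g_inverse = function(eta) clamp(plogis(eta)),
      mu_eta = function(eta) {
        p <- plogis(eta)
        ifelse(p > eps & p < 1 - eps, p * (1 - p), 0)
      },
      increasing = TRUE
    )
  )
  structure(c(list(name = name), spec), class = "link_spec")
}

#' @export
print.link_spec <- function(x, ...) {
  cat("<link_spec> ", x$name, if (!x$increasing) " (decreasing)", "\n", sep = "")
  invisible(x)
}

#' All five link specifications
#'
#' @param names Character vector of link names; defaults to all five.
#' @return Named list of [link_spec()] objects.
#' @export
all_links <- function(names = c("identity", "log", "log_complement", "odds", "logit")) {
  out <- lapply(names, link_spec)
  names(out) <- names
  out
}

as_link_list <- function(links) {
  if (inherits(links, "link_spec")) links <- list(links)
  if (is.character(links)) links <- lapply(links, link_spec)
  if (!length(links)) abort("at least one link function is required")
  stopifnot(all(vapply(links, inherits, logical(1), "link_spec")))
  names(links) <- vapply(links, `[[`, character(1), "name")
  links
}
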