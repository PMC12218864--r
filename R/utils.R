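#' @importFrom rlang %||% abort warn .data
#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom rpois rbeta rnbinom
#' @importFrom stats rmultinom dbinom dpois dnbinom plogis qlogis quantile sd
#' @importFrom stats var acf setNames rlnorm cor dist median
#' @importFrom utils head
NULL

# logit capped at +/-35: plogis(35) is 1 - 6e-16, i.e. exactly 1/0 to double
# precision without generating Inf in intermediate arithmetic.
LOGIT_CAP <- 35

clamp_logit <- function(x) pmin(pmax(x, -LOGIT_CAP), LOGIT_CAP)

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stopf("`%s` must be numeric and non-missing.", name)
  }
  lo_bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  hi_bad <- if (strict_upper) any(x >= upper) else any(x > upper)
  if (lo_bad || hi_bad) {
    stopf(
      "`%s` must lie in %s%s, %s%s.", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]"
    )
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be TRUE or FALSE.", name)
  }
  invisible(x)
}

# log(exp(a) + exp(b)) element-wise, stable
log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  # handle -Inf pairs
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' The twelve focal mammal species
#'
#' Registry of the focal species tracked by the pipeline, in the fixed
#' reporting order used by [effect_matrix()]: three Opuntia frugivores
#' (olive baboon, vervet monkey, elephant), seven other herbivores spanning
#' a range of body sizes, and two carnivores.
#'
#' @return A character vector of twelve species identifiers.
#' @export
#' @examples
#' focal_species()
focal_species <- function() {
  c(
    "olive_baboon", "vervet_monkey", "elephant",
    "buffalo", "dikdik", "impala", "greater_kudu",
    "reticulated_giraffe", "grevys_zebra", "plains_zebra",
    "spotted_hyena", "leopard"
  )
}
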