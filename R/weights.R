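#' Sliding-window weight functions
#'
#' The similarity score combines two weight functions: `w1` weights the
#' alike-in-state allele comparisons and `w2` the markers of the longest
#' common segment.  Besides the literal constants 0 and 1, the density
#' kinds are scaled to the window length `L` so that the total weight of
#' the symmetric window `[-L/2, L/2]` is 0.95:
#'
#' * `exponential`: rate lambda solves `1 - exp(-lambda * L/2) = 0.475`
#'   (0.475 mass on the positive half-window), density
#'   `lambda * exp(-lambda * |x|)` after symmetrization.  Chosen because
#'   linkage disequilibrium decays exponentially per generation.
#' * `laplace`: the same exponential family but a proper density
#'   `lambda/2 * exp(-lambda * |x|)` whose weight at x = 0 is below 1;
#'   lambda solves `1 - exp(-lambda * L/2) = 0.95`.
#' * `gaussian`: `N(0, sigma^2)` density with
#'   `sigma = (L/2) / qnorm(0.975)`, i.e. 0.95 mass on the window.
#' * `uniform_density`: constant `0.95 / L` on the window.
#' * `constant0`, `constant1`: literal 0 and 1.
#'
#' Outside the window every weight is 0.
#'
#' @param kind one of `"constant0"`, `"constant1"`, `"exponential"`,
#'   `"laplace"`, `"gaussian"`, `"uniform_density"`.
#' @param window_cM positive window length L in cM.
#' @return A function of the distance `x >= 0` to the window center with
#'   class `weight_fun` and attributes `kind`, `window_cM`, `param`.
#' @examples
#' w1 <- make_weight_function("exponential", 20)
#' attr(w1, "param")  # lambda = -log(0.525)/10
#' @export
make_weight_function <- function(kind = c("constant0", "constant1",
                                          "exponential", "laplace",
                                          "gaussian", "uniform_density"),
                                 window_cM) {
  kind <- match.arg(kind)
  if (!is.numeric(window_cM) || length(window_cM) != 1 || window_cM <= 0)
    stop("window_cM must be a positive number")
  H <- window_cM / 2
  fn <- switch(kind,
    constant0 = {
      param <- 0
      function(x) ifelse(abs(x) <= H, 0, 0)
    },
    constant1 = {
      param <- 1
      function(x) as.numeric(abs(x) <= H)
    },
    exponential = {
      param <- -log(1 - 0.475) / H
      function(x) ifelse(abs(x) <= H, param * exp(-param * abs(x)), 0)
    },
    laplace = {
      param <- -log(1 - 0.95) / H
      function(x) ifelse(abs(x) <= H, param / 2 * exp(-param * abs(x)), 0)
    },
    gaussian = {
      param <- H / stats::qnorm(0.975)
      function(x) ifelse(abs(x) <= H, stats::dnorm(x, 0, param), 0)
    },
    uniform_density = {
      param <- 0.95 / window_cM
      function(x) ifelse(abs(x) <= H, param, 0)
    })
  structure(fn, class = c("weight_fun", "function"),
            kind = kind, window_cM = window_cM,
            param = get("param", environment(fn)))
}

#' @export
print.weight_fun <- function(x, ...) {
  cat(sprintf("Weight function '%s', window %g cM, shape parameter %.5g\n",
              attr(x, "kind"), attr(x, "window_cM"), attr(x, "param")))
  invisible(x)
}
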