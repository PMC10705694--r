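#' @useDynLib pairf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rbeta qnorm pnorm plogis glm binomial
#'   fitted predict sd var pt qt p.adjust chisq.test quantile setNames
#'   aggregate complete.cases
#' @importFrom utils read.csv write.csv head
NULL

# Arm labels used throughout: treatment is binary with ECT coded 1, KET coded 0
# in model matrices; the prescriptive (interaction) effect is the ECT offset.
ARM_LEVELS <- c("ECT", "KET")

#' Derive a stage-specific seed from a global seed
#'
#' One global seed expands deterministically into per-stage seeds so that
#' simulation, fold assignment, bootstrap and permutation draws are
#' independently reproducible. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @param index integer sub-index (e.g. fold or replicate number).
#' @return an integer seed.
#' @export
spawn_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.double(seed)) * 48271 + h * 7919 + as.double(index) * 104729) %% 2147483629)
}

# round half away from zero (QIDS scores are integers; round() would round
# half to even, which biases a scale bounded at zero)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# evaluate a named coefficient map (optionally with "(Intercept)") against
# the columns of a data.frame
eval_linear <- function(df, coefs) {
  if (length(coefs) == 0L) return(rep(0, nrow(df)))
  nm <- names(coefs)
  if (is.null(nm) || any(nm == "")) {
    stop("coefficient maps must be fully named")
  }
  out <- rep(0, nrow(df))
  for (v in nm) {
    if (v == "(Intercept)") {
      out <- out + coefs[[v]]
    } else {
      if (!v %in% names(df)) {
        stop("coefficient map references undeclared predictor: ", v)
      }
      out <- out + coefs[[v]] * as.numeric(df[[v]])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(verbose, stage, ...) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(..., collapse = " ")))
  }
  invisible(NULL)
}
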