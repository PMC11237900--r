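#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd quantile cor cor.test wilcox.test lm confint
#'   coef rnorm runif setNames complete.cases p.adjust predict loess
#'   loess.control rt rbinom vcov update approx
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Geometric mean
#'
#' @param x positive numeric vector
#' @param na.rm drop missing values
#' @return geometric mean of `x`
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

## trapezoidal rule on (x, y) with x sorted increasing
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("trapezoid needs at least two points")
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## 95% HPD of a draws vector via coda
hpd_interval <- function(draws, prob = 0.95) {
  iv <- coda::HPDinterval(coda::as.mcmc(as.numeric(draws)), prob = prob)
  c(lower = iv[1, "lower"], upper = iv[1, "upper"])
}

## deterministic hash of an R object (md5 of its serialization)
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

## timestamped, level-tagged log line
log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...)))
}

## internal error helpers: classed conditions so callers can discriminate
stop_schema <- function(msg) stop(errorCondition(msg, class = c("lrasym_schema_error", "error")))
stop_integrity <- function(msg) stop(errorCondition(msg, class = c("lrasym_integrity_error", "error")))
stop_io <- function(msg) stop(errorCondition(msg, class = c("lrasym_io_error", "error")))
stop_input <- function(msg) stop(errorCondition(msg, class = c("lrasym_input_error", "error")))
stop_config <- function(msg) stop(errorCondition(msg, class = c("lrasym_config_error", "error")))
stop_domain <- function(msg) stop(errorCondition(msg, class = c("lrasym_domain_error", "error")))
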