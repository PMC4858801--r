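#' @importFrom stats approx coef lm median optimHess pchisq pnorm qchisq
#'   rbinom rnorm rpois runif sd setNames var nlminb AIC as.formula
#'   complete.cases aggregate cor
#' @importFrom utils head tail
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check that a value is a single finite number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Gamete identifiers are "<parent>-><offspring>" throughout: one per meiosis.
gamete_id <- function(parent, offspring) paste0(parent, "->", offspring)
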