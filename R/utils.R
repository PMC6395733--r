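# Internal helpers shared across the package.

#' Sentinel label for genes without an orthogroup assignment
#'
#' Genes whose orthogroup is unknown (or was removed by the smCOG size
#' filter) carry this reserved label. It is never a valid smCOG identifier:
#' unassigned genes keep their positions — so they still separate their
#' neighbours — but never contribute interactions.
#'
#' @format A length-one character vector.
#' @export
UNASSIGNED <- "UNASSIGNED"

#' Gene-level functional categories
#'
#' The five functional categories a gene may carry: core biosynthesis,
#' regulation, tailoring (scaffold-modifying enzymes), transport, and a
#' catch-all. smCOG-level categories additionally allow double labels
#' (e.g. "tailoring/core") and "mixed"; see [annotate_smcog_category()].
#'
#' @format Character vector of length 5.
#' @export
GENE_CATEGORIES <- c("core", "regulator", "tailoring", "transport", "other")

# Priority used to break exact ties between category shares (highest first).
CATEGORY_PRIORITY <- c("core", "tailoring", "transport", "regulator", "other")

# smCOG-level single categories (gene categories plus "mixed"); double
# categories are pairs of the gene-level entries.
MODULE_CATEGORIES <- c(GENE_CATEGORIES, "mixed")

is_unassigned <- function(x) x == UNASSIGNED

#' @importFrom rlang abort
abort_bgc <- function(msg, class) {
  rlang::abort(msg, class = c(class, "bgcmodules_error"))
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Exact binomial coefficient for moderate sizes: iterative multiply/divide,
# every intermediate an exact integer in double precision. Caller guards the
# magnitude (see .EXACT_LCHOOSE_MAX).
choose_exact <- function(n, k) {
  if (k < 0 || k > n) return(0)
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) {
    r <- r * (n - k + i)
    r <- r / i
  }
  r
}

# Largest log-denominator for which the exact integer path is used. Kept
# small enough that the running products above stay well below 2^53.
.EXACT_LCHOOSE_MAX <- log(1e9)

`%||%` <- function(a, b) if (is.null(a)) b else a
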