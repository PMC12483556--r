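#' Default 10-gene radiosensitivity signature
#'
#' Coefficients of the rank-based RSI signature (Eschrich et al. 2009,
#' Int J Radiat Oncol Biol Phys 75:489-496), as also implemented in the
#' public `hacksig` package. Within each sample the ten genes are ranked by
#' expression and RSI is the weighted sum of those ranks. Lower RSI =
#' more radiosensitive.
#'
#' @return Data frame with columns `gene` and `coefficient` (10 rows).
#' @examples
#' rsi_signature()
#' @export
rsi_signature <- function() {
  data.frame(
    gene = c("AR", "JUN", "STAT1", "PRKCB", "RELA",
             "ABL1", "SUMO1", "CDK1", "HDAC1", "IRF1"),
    coefficient = c(-0.0098009, 0.0128283, 0.0254552, -0.0017589, 0.0038171,
                    0.1070213, -0.0002509, -0.0092431, -0.0204469, -0.0441683),
    stringsAsFactors = FALSE
  )
}

validate_signature <- function(signature) {
  if (!is.data.frame(signature) ||
      !all(c("gene", "coefficient") %in% names(signature))) {
    stop("`signature` must be a data frame with columns `gene` and `coefficient`",
         call. = FALSE)
  }
  if (nrow(signature) != 10L) {
    stop("the RSI signature must have exactly 10 genes; got ",
         nrow(signature), call. = FALSE)
  }
  if (anyDuplicated(signature$gene)) {
    stop("duplicated gene symbols in signature", call. = FALSE)
  }
  if (!is.numeric(signature$coefficient) || any(!is.finite(signature$coefficient))) {
    stop("signature coefficients must be finite numbers", call. = FALSE)
  }
  invisible(signature)
}

#' Within-sample rank transform of an expression matrix
#'
#' Maps each sample's expression values to ranks 1..k ascending by
#' expression, with average ranks for ties. Ranking can be restricted to
#' the signature genes (the default scope for RSI scoring) or span the
#' whole matrix.
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns. No missing values.
#' @param scope `"signature"` (rank only the signature genes) or `"all"`
#'   (rank every gene, then subset downstream).
#' @param signature_genes Character vector of genes that must be present;
#'   required when `scope = "signature"`.
#'
#' @return Matrix of within-sample ranks with the same orientation; rows
#'   restricted to `signature_genes` when `scope = "signature"`.
#' @examples
#' m <- matrix(c(5, 1, 3), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
#' rank_transform(m, scope = "all")
#' @export
rank_transform <- function(mat, scope = c("signature", "all"),
                           signature_genes = NULL) {
  scope <- match.arg(scope)
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`mat` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (anyNA(mat)) stop("expression matrix contains missing values", call. = FALSE)
  if (is.null(rownames(mat))) stop("`mat` must have gene rownames", call. = FALSE)
  if (!is.null(signature_genes)) {
    missing_genes <- setdiff(signature_genes, rownames(mat))
    if (length(missing_genes)) {
      stop("signature gene(s) absent from expression matrix: ",
           paste(missing_genes, collapse = ", "), call. = FALSE)
    }
  }
  if (scope == "signature") {
    if (is.null(signature_genes)) {
      stop("`signature_genes` required when scope = \"signature\"", call. = FALSE)
    }
    mat <- mat[signature_genes, , drop = FALSE]
  }
  if (nrow(mat) < 2L) {
    stop("need at least 2 genes in the ranking scope", call. = FALSE)
  }
  ranks <- apply(mat, 2L, rank)  # average ranks for ties
  dimnames(ranks) <- dimnames(mat)
  ranks
}

#' Score RSI from an expression matrix
#'
#' Computes per-sample RSI as the weighted sum of within-sample gene ranks,
#' `rsi_s = sum_g coef_g * rank_{s,g}`, using a 10-gene signature. Scores
#' falling outside (0, 1] are clipped into \[0, 1\] with a warning; RSI is a
#' surviving fraction, so values outside that range indicate an expression
#' matrix on an unexpected scale or a non-standard signature.
#'
#' @param mat Numeric expression matrix, genes x samples.
#' @param signature Signature data frame (`gene`, `coefficient`);
#'   default [rsi_signature()].
#' @param rank_scope Passed to [rank_transform()]: rank within the 10
#'   signature genes (`"signature"`, default) or over the whole matrix
#'   (`"all"`).
#'
#' @return Named numeric vector of RSI values, one per sample.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(10 * 3), 10, 3,
#'             dimnames = list(rsi_signature()$gene, paste0("s", 1:3)))
#' score_rsi(m)
#' @export
score_rsi <- function(mat, signature = rsi_signature(),
                      rank_scope = c("signature", "all")) {
  rank_scope <- match.arg(rank_scope)
  validate_signature(signature)
  ranks <- rank_transform(mat, scope = rank_scope,
                          signature_genes = signature$gene)
  ranks <- ranks[signature$gene, , drop = FALSE]
  rsi <- as.numeric(crossprod(ranks, signature$coefficient))
  names(rsi) <- colnames(mat)
  if (any(!is.finite(rsi))) {
    stop("non-finite RSI score(s) produced; check signature coefficients",
         call. = FALSE)
  }
  out_of_range <- rsi <= 0 | rsi > 1
  if (any(out_of_range)) {
    warning(sum(out_of_range), " RSI score(s) outside (0, 1] clipped into [0, 1]",
            call. = FALSE)
    rsi <- pmin(pmax(rsi, 0), 1)
  }
  rsi
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited expression matrix
#'
#' Expects genes in rows (first column = gene identifier) and a header row
#' of sample identifiers. Tab or comma separated, sniffed from the first
#' line.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                         row.names = 1, check.names = FALSE)
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("expression matrix is not numeric", call. = FALSE)
  if (anyNA(m)) stop("expression matrix contains missing values", call. = FALSE)
  if (anyDuplicated(rownames(m))) {
    stop("duplicated gene identifiers in expression matrix", call. = FALSE)
  }
  m
}

#' Read a signature coefficient file
#'
#' Delimited text with columns `gene` and `coefficient`.
#'
#' @param path File path.
#' @return Data frame usable as the `signature` argument of [score_rsi()].
#' @export
read_signature <- function(path) {
  s <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                         stringsAsFactors = FALSE)
  if (ncol(s) == 2L && !all(c("gene", "coefficient") %in% names(s))) {
    names(s) <- c("gene", "coefficient")
  }
  validate_signature(s)
  s
}
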