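#' Row-normalize an expression matrix
#'
#' Linearly rescales each gene row to mean 0 and a fixed standard deviation
#' (default 3), the convention used for heat-map display of two-class
#' expression data. Zero-variance genes cannot be scaled and are excluded
#' with a warning; the dropped ids are recorded in the `"excluded"`
#' attribute.
#'
#' @param mat Numeric genes x samples matrix (>= 2 samples).
#' @param target_sd Target row SD (default 3).
#' @return Normalized matrix (possibly fewer rows), with attribute
#'   `"excluded"` listing dropped gene ids.
#' @export
normalize_expression <- function(mat, target_sd = 3) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples per gene")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("gene", seq_len(nrow(mat)))
  sds <- apply(mat, 1, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    warning(sum(zero), " zero-variance gene(s) excluded: ",
            paste(utils::head(rownames(mat)[zero], 5), collapse = ", "))
  out <- mat[!zero, , drop = FALSE]
  out <- (out - rowMeans(out)) / apply(out, 1, stats::sd) * target_sd
  attr(out, "excluded") <- rownames(mat)[zero]
  out
}

#' Signal-to-noise ranking score for two groups
#'
#' The two-class ranking metric `(mean_A - mean_B) / (sd_A + sd_B)` with
#' sample SDs (n - 1 denominator). Positive scores mean higher expression in
#' group A; swapping the groups negates the score. An optional SD floor
#' (`sd >= 0.2 * |mean|`, the floored variant used by some enrichment tools)
#' is available behind `sd_floor`.
#'
#' @param groupA,groupB Numeric vectors (>= 2 values each).
#' @param sd_floor If `TRUE`, floor each SD at 0.2 x |group mean|.
#' @return The signal-to-noise score.
#' @examples
#' signal_to_noise(c(1, 2, 3), c(4, 5, 6)) # -1.5
#' @export
signal_to_noise <- function(groupA, groupB, sd_floor = FALSE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need at least 2 samples per group")
  mA <- mean(groupA); mB <- mean(groupB)
  sA <- stats::sd(groupA); sB <- stats::sd(groupB)
  if (sd_floor) {
    sA <- max(sA, 0.2 * abs(mA))
    sB <- max(sB, 0.2 * abs(mB))
  }
  if (sA + sB == 0) stop("zero spread in both groups: score undefined")
  (mA - mB) / (sA + sB)
}

#' Rank genes by two-class signal-to-noise
#'
#' One score per gene, sorted descending (most A-upregulated first); ties
#' broken by gene id for determinism.
#'
#' @param mat Numeric genes x samples matrix with row names.
#' @param class_labels Vector of sample class labels; exactly two classes.
#' @param group_order Optional length-2 vector naming which class is A and
#'   which is B; defaults to sorted unique labels.
#' @param sd_floor Passed to [signal_to_noise()].
#' @return `data.frame` with `gene_id` and `score`, sorted descending.
#' @export
rank_genes <- function(mat, class_labels, group_order = NULL,
                       sd_floor = FALSE) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("gene", seq_len(nrow(mat)))
  if (length(class_labels) != ncol(mat))
    stop("one class label per sample required")
  lev <- sort(unique(as.character(class_labels)))
  if (length(lev) != 2)
    stop("exactly two classes required, got ", length(lev))
  if (!is.null(group_order)) {
    if (!setequal(group_order, lev)) stop("group_order must name both classes")
    lev <- group_order
  }
  ia <- class_labels == lev[1]; ib <- class_labels == lev[2]
  score <- apply(mat, 1, function(r)
    signal_to_noise(r[ia], r[ib], sd_floor = sd_floor))
  out <- data.frame(gene_id = rownames(mat), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "group_order") <- lev
  out
}

#' Read a genes-x-samples expression matrix with a class-label header
#'
#' Tab-delimited text: first row `gene_id<TAB>label1<TAB>label2...` giving
#' per-sample class labels, subsequent rows gene id then values.
#'
#' @param path File path.
#' @return List with `mat` (numeric matrix) and `class_labels`.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file needs a label row and data")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- utils::read.delim(text = lines[-1], header = FALSE,
                            stringsAsFactors = FALSE)
  mat <- as.matrix(body[, -1, drop = FALSE])
  rownames(mat) <- body[[1]]
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  list(mat = mat, class_labels = hdr[-1])
}
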