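# Differential-expression calling: SAM-style permutation testing, fold-change
# majority rule, Connectivity-Map amplitude statistic, and cross-dataset
# signature combination.

#' Build a two-class expression profile
#'
#' @param matrix Numeric genes x samples matrix with gene identifiers as row
#'   names.
#' @param class_labels Character vector (one per column) in
#'   \code{c("treatment", "control")}; ignored for double-channel data.
#' @param channel_mode \code{"single"} (separate treatment/control columns) or
#'   \code{"double"} (each column is already a per-sample treatment/control
#'   ratio; no control columns).
#' @param log2_scale \code{TRUE} if values are log2-transformed. Fold-change
#'   and amplitude callers unlog (2^x) before applying their linear-scale
#'   rules; the SAM caller tests the matrix as given when already on log
#'   scale and log2(x+1)-transforms it otherwise.
#' @return An object of class \code{ExpressionProfile}.
#' @export
expression_profile <- function(matrix, class_labels = NULL,
                               channel_mode = c("single", "double"),
                               log2_scale = FALSE) {
  channel_mode <- match.arg(channel_mode)
  if (is.null(rownames(matrix))) stop("expression matrix needs gene row names")
  if (anyDuplicated(rownames(matrix))) stop("gene identifiers must be unique")
  if (channel_mode == "single") {
    if (is.null(class_labels) || length(class_labels) != ncol(matrix))
      stop("one class label per sample is required for single-channel data")
    if (!all(class_labels %in% c("treatment", "control")))
      stop("class labels must be 'treatment' or 'control'")
    if (!any(class_labels == "treatment") || !any(class_labels == "control"))
      stop("single-channel data needs at least one sample in each class")
  }
  structure(list(matrix = matrix, class_labels = class_labels,
                 channel_mode = channel_mode, log2_scale = log2_scale),
            class = "ExpressionProfile")
}

#' @export
print.ExpressionProfile <- function(x, ...) {
  cat("ExpressionProfile:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples,", x$channel_mode, "channel",
      if (x$log2_scale) "(log2 scale)" else "(linear scale)", "\n")
  if (x$channel_mode == "single")
    cat("  classes:", sum(x$class_labels == "treatment"), "treatment /",
        sum(x$class_labels == "control"), "control\n")
  invisible(x)
}

#' Read an expression matrix and sample sheet
#'
#' Expression TSV: first column gene id, remaining columns samples. Sample
#' sheet TSV: columns \code{sample}, \code{class} and optionally
#' \code{dataset_id}.
#'
#' @param expr_path Path to the expression TSV.
#' @param sheet_path Path to the sample sheet TSV, or \code{NULL} for
#'   double-channel data.
#' @param channel_mode,log2_scale Passed to \code{\link{expression_profile}}.
#' @return An \code{ExpressionProfile}.
#' @export
read_expression <- function(expr_path, sheet_path = NULL,
                            channel_mode = "single", log2_scale = FALSE) {
  tab <- utils::read.delim(expr_path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  labels <- NULL
  if (!is.null(sheet_path)) {
    sheet <- utils::read.delim(sheet_path)
    labels <- sheet$class[match(colnames(m), sheet$sample)]
  }
  expression_profile(m, labels, channel_mode, log2_scale)
}

#' Construct an up/down gene signature
#'
#' Genes appearing in both directions (conflict genes) are discarded.
#'
#' @param entity_id Small-molecule or miRNA identifier.
#' @param up,down Character vectors of gene identifiers.
#' @return An object of class \code{SignatureSet}.
#' @export
signature_set <- function(entity_id, up = character(0), down = character(0)) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  conflict <- intersect(up, down)
  structure(list(entity_id = entity_id,
                 up = sort(setdiff(up, conflict)),
                 down = sort(setdiff(down, conflict))),
            class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat("SignatureSet", x$entity_id, ":", length(x$up), "up /",
      length(x$down), "down genes\n")
  invisible(x)
}

#' All genes in a signature, either direction
#' @param sig A \code{SignatureSet}.
#' @return Character vector of gene ids.
#' @export
signature_genes <- function(sig) sort(c(sig$up, sig$down))

#' Connectivity-Map amplitude statistic
#'
#' \code{A = (t - c) / ((t + c) / 2)} for non-negative treatment and control
#' values, bounded in (-2, 2). |A| = 2/3 corresponds to an exact 2-fold
#' change: A > 2/3 means up-regulation, A < -2/3 down-regulation. Vectorised;
#' t = c = 0 gives NA (such probes are skipped by callers).
#'
#' @param t Treatment expression value(s), >= 0.
#' @param c Control expression value(s), >= 0.
#' @return Amplitude value(s).
#' @export
amplitude <- function(t, c) {
  if (any(t < 0, na.rm = TRUE) || any(c < 0, na.rm = TRUE))
    stop("amplitude requires non-negative expression values")
  out <- (t - c) / ((t + c) / 2)
  out[t == 0 & c == 0] <- NA_real_
  out
}

# linear-scale matrix regardless of input scale
linear_matrix <- function(profile) {
  if (profile$log2_scale) 2^profile$matrix else profile$matrix
}

#' SAM-style differential expression caller
#'
#' A simplified significance-analysis-of-microarrays procedure for unpaired
#' two-class designs: per-gene statistic
#' \code{d = (mean_t - mean_c) / (s + s0)} where s is the pooled standard
#' error and the exchangeability constant s0 is the median of all gene-wise
#' standard errors. The false discovery rate at each candidate |d| threshold
#' is estimated from class-label permutations (the identity permutation is
#' included), and the most permissive threshold with estimated FDR at or
#' below \code{fdr_cutoff} is applied. Testing is done on the log2 scale.
#'
#' @param profile Single-channel \code{ExpressionProfile} with >= 2 samples
#'   per class.
#' @param fdr_cutoff Permutation-FDR threshold (default 0.05).
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed for the permutations.
#' @return A \code{SignatureSet} (up: mean_t > mean_c among called genes).
#' @export
call_de_sam <- function(profile, fdr_cutoff = 0.05, n_perm = 100L, seed = 1L) {
  stopifnot(inherits(profile, "ExpressionProfile"))
  if (profile$channel_mode != "single")
    stop("SAM calling requires single-channel data")
  labels <- profile$class_labels
  if (sum(labels == "treatment") < 2L || sum(labels == "control") < 2L)
    stop("SAM calling needs >= 2 samples per class; use the fold-change caller")
  m <- profile$matrix
  if (!profile$log2_scale) m <- log2(m + 1)

  d_stat <- function(mat, lab) {
    it <- lab == "treatment"; ic <- !it
    n1 <- sum(it); n2 <- sum(ic)
    m1 <- rowMeans(mat[, it, drop = FALSE])
    m2 <- rowMeans(mat[, ic, drop = FALSE])
    v1 <- rowSums((mat[, it, drop = FALSE] - m1)^2)
    v2 <- rowSums((mat[, ic, drop = FALSE] - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) * (v1 + v2) / (n1 + n2 - 2))
    list(diff = m1 - m2, s = s)
  }
  # zero-variance genes with zero difference carry no evidence: d = 0
  d_of <- function(st, s0) {
    d <- st$diff / (st$s + s0)
    d[st$diff == 0] <- 0
    d
  }

  obs <- d_stat(m, labels)
  s0 <- stats::median(obs$s)
  d_obs <- d_of(obs, s0)

  set.seed(seed)
  n <- ncol(m)
  perm_abs <- matrix(0, n_perm, nrow(m))
  perm_abs[1L, ] <- abs(d_obs)                       # identity permutation
  for (b in seq_len(n_perm)[-1L]) {
    lab <- labels[sample.int(n)]
    perm_abs[b, ] <- abs(d_of(d_stat(m, lab), s0))
  }

  # most permissive |d| threshold with estimated FDR <= cutoff
  cand <- sort(unique(abs(d_obs)), decreasing = TRUE)
  chosen <- Inf
  for (thr in cand) {
    r <- sum(abs(d_obs) >= thr)
    v <- mean(rowSums(perm_abs >= thr))
    if (min(1, v / r) <= fdr_cutoff) chosen <- thr else break
  }
  called <- abs(d_obs) >= chosen
  genes <- rownames(m)
  signature_set(entity_id = NA_character_,
                up = genes[called & obs$diff > 0],
                down = genes[called & obs$diff < 0])
}

#' Fold-change differential expression caller
#'
#' For single-channel data with a singleton class, each treatment sample is
#' compared with the mean of the control samples: a gene is up in that sample
#' if the ratio is >= 2 and down if <= 1/2. For double-channel data each
#' column already holds per-sample ratios and the same thresholds apply. A
#' gene is called only when it moves in the same direction in strictly more
#' than half of its evaluable samples; samples with a non-positive required
#' control value are skipped for that gene. Conflict genes are removed.
#'
#' @param profile An \code{ExpressionProfile}.
#' @return A \code{SignatureSet}.
#' @export
call_de_foldchange <- function(profile) {
  stopifnot(inherits(profile, "ExpressionProfile"))
  ratios <- fold_ratios(profile)
  up_n <- rowSums(ratios >= 2, na.rm = TRUE)
  down_n <- rowSums(ratios <= 0.5, na.rm = TRUE)
  evaluable <- rowSums(!is.na(ratios))
  signature_set(entity_id = NA_character_,
                up = rownames(ratios)[up_n > evaluable / 2],
                down = rownames(ratios)[down_n > evaluable / 2])
}

#' Amplitude differential expression caller
#'
#' Connectivity-Map style calling: each treatment sample is compared with the
#' mean of the matched controls via \code{\link{amplitude}}; a gene is up in
#' a sample when A > \code{cutoff} (default 2/3, i.e. strictly more than a
#' 2-fold change) and down when A < -\code{cutoff}, then the same strict
#' majority and conflict rules as the fold-change caller apply.
#'
#' @param profile An \code{ExpressionProfile}.
#' @param cutoff Amplitude cutoff, default \code{2/3}.
#' @return A \code{SignatureSet}.
#' @export
call_de_amplitude <- function(profile, cutoff = 2 / 3) {
  stopifnot(inherits(profile, "ExpressionProfile"))
  m <- linear_matrix(profile)
  if (profile$channel_mode == "double") {
    # columns are ratios t/c; amplitude of (r, 1) preserves the rule
    a <- amplitude(m, matrix(1, nrow(m), ncol(m)))
  } else {
    ctrl <- rowMeans(m[, profile$class_labels == "control", drop = FALSE])
    tr <- m[, profile$class_labels == "treatment", drop = FALSE]
    a <- amplitude(tr, matrix(ctrl, nrow(tr), ncol(tr)))
  }
  up_n <- rowSums(a > cutoff, na.rm = TRUE)
  down_n <- rowSums(a < -cutoff, na.rm = TRUE)
  evaluable <- rowSums(!is.na(a))
  signature_set(entity_id = NA_character_,
                up = rownames(m)[up_n > evaluable / 2],
                down = rownames(m)[down_n > evaluable / 2])
}

fold_ratios <- function(profile) {
  m <- linear_matrix(profile)
  if (profile$channel_mode == "double") return(m)
  ctrl_cols <- profile$class_labels == "control"
  ctrl <- rowMeans(m[, ctrl_cols, drop = FALSE])
  tr <- m[, !ctrl_cols, drop = FALSE]
  ratios <- tr / ctrl
  ratios[ctrl <= 0, ] <- NA_real_    # non-positive control: skip gene/sample
  ratios
}

#' Combine per-dataset signatures for one entity
#'
#' A gene keeps a direction when it is called in that direction in at least
#' \code{min_support} of the input signatures; genes qualifying in both
#' directions are discarded as conflicts.
#'
#' @param signatures List of \code{SignatureSet} objects for one entity.
#' @param min_support Minimum number of supporting signatures (default 2).
#' @param entity_id Identifier for the combined signature; defaults to the
#'   first non-missing input identifier.
#' @return A combined \code{SignatureSet}.
#' @export
combine_signatures <- function(signatures, min_support = 2L, entity_id = NULL) {
  stopifnot(length(signatures) >= 1L)
  if (is.null(entity_id)) {
    ids <- vapply(signatures, function(s) s$entity_id, "")
    entity_id <- if (any(!is.na(ids))) ids[!is.na(ids)][1L] else NA_character_
  }
  up_tab <- table(unlist(lapply(signatures, `[[`, "up")))
  down_tab <- table(unlist(lapply(signatures, `[[`, "down")))
  up <- names(up_tab)[up_tab >= min_support]
  down <- names(down_tab)[down_tab >= min_support]
  signature_set(entity_id, up = up, down = down)
}

#' Write signatures as a long TSV (entity, gene, direction)
#'
#' @param signatures List of \code{SignatureSet} objects.
#' @param path Output TSV path.
#' @export
write_signatures <- function(signatures, path) {
  rows <- do.call(rbind, lapply(signatures, function(s) {
    data.frame(entity = s$entity_id,
               gene = c(s$up, s$down),
               direction = rep(c("up", "down"), c(length(s$up), length(s$down))),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read signatures from a long TSV (entity, gene, direction)
#'
#' @param path TSV path with columns \code{entity}, \code{gene},
#'   \code{direction}.
#' @return Named list of \code{SignatureSet} objects.
#' @export
read_signatures <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$entity), function(d) {
    signature_set(d$entity[1L],
                  up = d$gene[d$direction == "up"],
                  down = d$gene[d$direction == "down"])
  })
  out[order(names(out))]
}
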