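#' Median-of-ratios size factors
#'
#' Library-size normalization by the median-of-ratios convention: a
#' geometric-mean pseudo-reference is built over genes with nonzero
#' counts in every sample, and each sample's factor is the median ratio
#' of its counts to the reference over those genes.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  elig <- rowSums(counts > 0) == ncol(counts)
  if (!any(elig)) stop("no gene has nonzero counts in all samples")
  lref <- rowMeans(log(counts[elig, , drop = FALSE]))
  apply(counts[elig, , drop = FALSE], 2L,
        function(col) exp(stats::median(log(col) - lref)))
}

#' Simplified negative-binomial enrichment test
#'
#' Per-gene IP-versus-input enrichment on normalized counts: the log2
#' ratio of condition means with a stabilizing pseudo-count, a
#' method-of-moments negative-binomial dispersion shrunk toward the
#' across-gene median, and a Wald test on the log ratio. Because the
#' moderated dispersion borrows strength across genes, the Wald
#' statistic is referred to a t distribution with
#' (n1 + n2 - 2 + `prior_df`) degrees of freedom; the default prior df
#' was set by null-simulation calibration so that raw p-values are
#' approximately uniform at realistic dispersions. BH adjustment across
#' tested genes. This is deliberately a simple, transparent test — it
#' does not replicate any particular DE tool's shrinkage machinery, and
#' externally produced DE tables can be fed directly to the downstream
#' steps instead.
#'
#' @param counts integer matrix, genes x samples.
#' @param condition factor/character per sample.
#' @param ip,reference condition labels contrasted (IP over reference).
#' @param pseudo_count added to normalized means (default 0.5).
#' @param dispersion_shrink weight on the across-gene median dispersion
#'   in \[0, 1\] (default 0.8; few replicates make per-gene estimates
#'   unstable).
#' @param prior_df extra degrees of freedom credited to the moderated
#'   dispersion (default 16).
#' @return data.frame: `gene_id`, `base_mean`, `log2FC`, `p`, `padj`,
#'   `tested` (all-zero genes are excluded from testing and reported
#'   with NA statistics; a message gives their number).
#' @export
enrichment_test <- function(counts, condition, ip = "tdp_ip",
                            reference = "input", pseudo_count = 0.5,
                            dispersion_shrink = 0.8, prior_df = 16) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(counts))
  sel <- condition %in% c(ip, reference)
  counts <- counts[, sel, drop = FALSE]
  condition <- condition[sel]
  n1 <- sum(condition == ip); n2 <- sum(condition == reference)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least two replicates in each condition")
  }
  gene_id <- rownames(counts) %||% sprintf("gene%05d", seq_len(nrow(counts)))
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  a <- norm[, condition == ip, drop = FALSE]
  b <- norm[, condition == reference, drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, stats::var); v2 <- apply(b, 1L, stats::var)
  tested <- m1 + m2 > 0
  if (any(!tested)) {
    message(sum(!tested), " all-zero gene(s) excluded from testing")
  }
  # method-of-moments dispersion, pooled over conditions, shrunk to the
  # across-gene median
  disp_g <- pmax(0, ((v1 - m1) + (v2 - m2)) /
                   pmax(m1^2 + m2^2, .Machine$double.eps))
  disp0 <- stats::median(disp_g[tested & disp_g > 0])
  if (!is.finite(disp0)) disp0 <- 0.01
  disp <- (1 - dispersion_shrink) * disp_g + dispersion_shrink * disp0
  l1 <- log(m1 + pseudo_count); l2 <- log(m2 + pseudo_count)
  se <- sqrt((1 / (m1 + pseudo_count) + disp) / n1 +
               (1 / (m2 + pseudo_count) + disp) / n2)
  tstat <- (l1 - l2) / se
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2 + prior_df)
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- bh_adjust(p[tested])
  data.frame(gene_id = gene_id,
             base_mean = (m1 + m2) / 2,
             log2FC = ifelse(tested, (l1 - l2) / log(2), NA_real_),
             p = p, padj = padj, tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Subtract tag-only control enrichment
#'
#' Removes nonspecific (tag-only pull-down) enrichment by subtracting the
#' YFP-control log2 fold change from each gene's log2 fold change,
#' matched by gene id. Genes absent from the control table get a control
#' value of 0 and are flagged (`yfp_missing`).
#'
#' @param tdp_records data.frame with `gene_id` and `log2FC`.
#' @param yfp_records data.frame with `gene_id` and `log2FC` from the
#'   tag-only IP.
#' @return `tdp_records` with added `yfp_log2FC`, `adjusted_log2FC`
#'   (= log2FC - yfp_log2FC) and `yfp_missing` columns.
#' @export
yfp_subtract <- function(tdp_records, yfp_records) {
  stopifnot(all(c("gene_id", "log2FC") %in% names(tdp_records)),
            all(c("gene_id", "log2FC") %in% names(yfp_records)))
  idx <- match(tdp_records$gene_id, yfp_records$gene_id)
  out <- tdp_records
  out$yfp_log2FC <- ifelse(is.na(idx), 0, yfp_records$log2FC[idx])
  out$yfp_missing <- is.na(idx)
  out$adjusted_log2FC <- out$log2FC - out$yfp_log2FC
  out
}

#' Candidate filter at the printed enrichment thresholds
#'
#' Strict inequalities, matching the published definition: log2FC
#' strictly above `log2fc_min` (a gene at exactly 1 is excluded) and
#' adjusted p strictly below `padj_max`. `mode` selects the raw or
#' YFP-subtracted fold change.
#'
#' @param records enrichment data.frame with `gene_id`, `padj`, and
#'   `log2FC` (and `adjusted_log2FC` for `mode = "adjusted"`).
#' @param log2fc_min,padj_max thresholds (defaults 1 and 0.05).
#' @param mode filter on `log2FC` ("raw", default) or
#'   `adjusted_log2FC` ("adjusted").
#' @return character vector of candidate gene ids.
#' @export
candidate_filter <- function(records, log2fc_min = 1, padj_max = 0.05,
                             mode = c("raw", "adjusted")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) return(character(0))
  fc <- if (mode == "raw") records$log2FC else records$adjusted_log2FC
  sel <- !is.na(fc) & !is.na(records$padj) &
    fc > log2fc_min & records$padj < padj_max
  records$gene_id[sel]
}

#' Set-overlap bookkeeping between two candidate lists
#'
#' Exact set algebra between two candidate sets given either as id
#' vectors or as sizes with a shared count. Percentages are carried at
#' full precision; round for reporting.
#'
#' @param a,b character vectors of ids, or (with `shared`) integer sizes.
#' @param shared intersection size when `a` and `b` are sizes.
#' @return one-row data.frame: `size_a`, `size_b`, `shared`, `unique_a`,
#'   `unique_b`, `union`, `pct_shared_of_a`, `pct_shared_of_b`.
#' @examples
#' overlap_report(1055, 1393, shared = 876)  # union 1572, 83% / 63%
#' @export
overlap_report <- function(a, b, shared = NULL) {
  if (is.null(shared)) {
    a <- unique(as.character(a)); b <- unique(as.character(b))
    shared <- length(intersect(a, b))
    size_a <- length(a); size_b <- length(b)
  } else {
    stopifnot(length(a) == 1L, length(b) == 1L, a >= 0, b >= 0)
    size_a <- as.numeric(a); size_b <- as.numeric(b)
    if (shared > min(size_a, size_b)) {
      stop("shared cannot exceed the smaller set")
    }
  }
  data.frame(size_a = size_a, size_b = size_b, shared = shared,
             unique_a = size_a - shared, unique_b = size_b - shared,
             union = size_a + size_b - shared,
             pct_shared_of_a = 100 * shared / size_a,
             pct_shared_of_b = 100 * shared / size_b)
}

#' Delta-delta-Ct fold change
#'
#' Relative qPCR quantification: replicate wells are averaged per
#' condition, delta Ct = Ct(target) - Ct(reference gene) within each
#' condition, delta-delta Ct = delta Ct(IP) - delta Ct(input), and fold
#' change = 2^(-delta-delta Ct). Identities: fold change 1 at
#' delta-delta Ct 0, and log2(fold change) = -delta-delta Ct exactly.
#'
#' @param target_ip,reference_ip Ct values (replicate wells) for the
#'   target and reference gene in the IP sample.
#' @param target_input,reference_input same for the input sample.
#' @return one-row data.frame: `delta_ct_ip`, `delta_ct_input`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
ddct_fold_change <- function(target_ip, reference_ip, target_input,
                             reference_input) {
  vals <- c(target_ip, reference_ip, target_input, reference_input)
  if (!all(is.finite(vals))) stop("Ct values must be finite")
  d_ip <- mean(target_ip) - mean(reference_ip)
  d_in <- mean(target_input) - mean(reference_input)
  ddct <- d_ip - d_in
  data.frame(delta_ct_ip = d_ip, delta_ct_input = d_in,
             delta_delta_ct = ddct, fold_change = 2^(-ddct))
}

#' Join fly genes to human orthologs
#'
#' Left join of fly enrichment records onto a supplied ortholog table
#' (fly_id, human_id, score). Many-to-many mappings are preserved (with
#' a message); unmapped genes are retained with `NA` ortholog. Optionally
#' keep only each gene's best-scoring ortholog(s).
#'
#' @param fly_records data.frame with a `gene_id` column.
#' @param ortholog_table data.frame with `fly_id`, `human_id`, `score`.
#' @param best_score_only keep only rows with the maximal score per fly
#'   gene (ties kept).
#' @return joined data.frame.
#' @export
ortholog_join <- function(fly_records, ortholog_table,
                          best_score_only = FALSE) {
  stopifnot("gene_id" %in% names(fly_records),
            all(c("fly_id", "human_id", "score") %in% names(ortholog_table)))
  ot <- ortholog_table
  if (best_score_only) {
    keep <- unlist(lapply(split(seq_len(nrow(ot)), ot$fly_id), function(i) {
      i[ot$score[i] == max(ot$score[i])]
    }), use.names = FALSE)
    ot <- ot[sort(keep), , drop = FALSE]
  }
  dup <- sum(duplicated(ot$fly_id))
  if (dup > 0) {
    message(dup, " fly gene(s) map to multiple orthologs; ",
            "all mappings retained")
  }
  out <- merge(fly_records, ot, by.x = "gene_id", by.y = "fly_id",
               all.x = TRUE, sort = FALSE)
  out
}

#' Compare expression between cryptic-exon and canonical nuclei
#'
#' Two-sample t test (pooled variance by default, mirroring the usual
#' independent-t-test default) of a gene's log-normalized expression
#' between nuclei carrying TDP-43-associated cryptic exons and nuclei
#' with canonical splice junctions. The t statistic is signed as first
#' group (order of appearance) minus second.
#'
#' @param data data.frame with a `group` column (exactly two groups) and
#'   the expression column named by `gene`.
#' @param gene name of the expression column (default "expr").
#' @param var_equal pooled-variance t (default TRUE); FALSE gives Welch.
#' @return list with `means` (named group means), `test` (data.frame
#'   statistic, df, p_value, method), and `per_nucleus` (the input
#'   columns, violin-ready).
#' @export
cryptic_group_compare <- function(data, gene = "expr", var_equal = TRUE) {
  stopifnot("group" %in% names(data), gene %in% names(data))
  groups <- unique(as.character(data$group))
  if (length(groups) < 2L) stop("need two groups to compare")
  if (length(groups) > 2L) stop("exactly two groups expected")
  x <- data[[gene]][data$group == groups[1L]]
  y <- data[[gene]][data$group == groups[2L]]
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(
    means = stats::setNames(c(mean(x), mean(y)), groups),
    test = data.frame(statistic = unname(tt$statistic),
                      df = unname(tt$parameter), p_value = tt$p.value,
                      method = if (var_equal) "two-sample t (pooled)"
                               else "Welch t",
                      stringsAsFactors = FALSE),
    per_nucleus = data[, c("group", gene)]
  )
}
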