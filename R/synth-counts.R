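#' Parameters for the RNA-IP count simulator
#'
#' Emulates gene-level count tables for input (whole-brain transcriptome),
#' TDP-43 IP and tag-only (YFP) IP libraries: negative-binomial counts
#' with mean `baseline * size_factor * 2^log2FC`, where the planted
#' `enriched_log2fc` applies to `enriched_set` genes in the TDP IP only
#' and `nonspecific_log2fc` to `nonspecific_set` genes in the YFP IP only.
#'
#' @param n_genes number of genes.
#' @param n_reps biological replicates per condition (default 3).
#' @param baseline_meanlog,baseline_sdlog log-normal distribution of
#'   per-gene baseline means.
#' @param size_factors per-sample library scale factors, length
#'   `3 * n_reps` (input, TDP IP, YFP IP), or a single value recycled.
#' @param dispersion negative-binomial dispersion (Var = mu + a mu^2).
#' @param enriched_set integer indices of truly TDP-enriched genes.
#' @param enriched_log2fc planted log2 enrichment of those genes.
#' @param nonspecific_set indices of genes enriched in the YFP control.
#' @param nonspecific_log2fc planted log2 enrichment in the YFP IP.
#' @param seed integer RNG seed.
#' @return object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes = 2000, n_reps = 3,
                             baseline_meanlog = log(100),
                             baseline_sdlog = 1,
                             size_factors = 1, dispersion = 0.05,
                             enriched_set = integer(0),
                             enriched_log2fc = 3,
                             nonspecific_set = integer(0),
                             nonspecific_log2fc = 2, seed = 1) {
  stopifnot(n_genes >= 1, n_reps >= 2, dispersion > 0,
            is.finite(enriched_log2fc), is.finite(nonspecific_log2fc),
            all(enriched_set >= 1 & enriched_set <= n_genes),
            all(nonspecific_set >= 1 & nonspecific_set <= n_genes))
  structure(list(n_genes = n_genes, n_reps = n_reps,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 size_factors = size_factors, dispersion = dispersion,
                 enriched_set = as.integer(enriched_set),
                 enriched_log2fc = enriched_log2fc,
                 nonspecific_set = as.integer(nonspecific_set),
                 nonspecific_log2fc = nonspecific_log2fc, seed = seed),
            class = "count_sim_params")
}

#' Simulate RNA-IP count tables
#'
#' @param params a [count_sim_params()] object.
#' @return list with `counts` (integer matrix genes x samples),
#'   `condition` (factor: input / tdp_ip / yfp_ip per sample), `truth`
#'   (data.frame gene_id, baseline, log2fc_tdp, log2fc_yfp), `params`.
#' @export
gen_counts <- function(params) {
  stopifnot(inherits(params, "count_sim_params"))
  p <- params
  n_samp <- 3L * p$n_reps
  sf <- rep_len(p$size_factors, n_samp)
  condition <- factor(rep(c("input", "tdp_ip", "yfp_ip"), each = p$n_reps),
                      levels = c("input", "tdp_ip", "yfp_ip"))
  with_seed(stream_seed(p$seed, "counts"), {
    baseline <- stats::rlnorm(p$n_genes, p$baseline_meanlog,
                              p$baseline_sdlog)
    l2_tdp <- numeric(p$n_genes); l2_tdp[p$enriched_set] <- p$enriched_log2fc
    l2_yfp <- numeric(p$n_genes)
    l2_yfp[p$nonspecific_set] <- p$nonspecific_log2fc
    lfc <- cbind(input = 0, tdp_ip = l2_tdp, yfp_ip = l2_yfp)
    counts <- matrix(0L, p$n_genes, n_samp)
    for (j in seq_len(n_samp)) {
      mu <- baseline * sf[j] * 2^lfc[, as.character(condition[j])]
      counts[, j] <- stats::rnbinom(p$n_genes, mu = mu,
                                    size = 1 / p$dispersion)
    }
    rownames(counts) <- sprintf("gene%05d", seq_len(p$n_genes))
    colnames(counts) <- paste0(condition, "_", rep(seq_len(p$n_reps), 3))
    list(counts = counts, condition = condition,
         truth = data.frame(gene_id = rownames(counts),
                            baseline = baseline, log2fc_tdp = l2_tdp,
                            log2fc_yfp = l2_yfp,
                            stringsAsFactors = FALSE),
         params = p)
  })
}

#' Simulate a single-gene nucleus-by-group expression table
#'
#' Emulates the patient snRNA-seq comparison: log-normalized expression of
#' one gene in nuclei carrying cryptic exons versus nuclei with canonical
#' splice junctions. Defaults reproduce the study conditions (87 cryptic
#' and 377 canonical nuclei; group means 1.65 and 1.35; common within
#' group standard deviation 0.8, a realistic spread for log-normalized
#' single-nucleus data).
#'
#' @param n_cryptic,n_canonical group sizes.
#' @param mean_cryptic,mean_canonical group means (log-normalized units).
#' @param sd common within-group standard deviation.
#' @param seed integer RNG seed.
#' @return data.frame with `nucleus_id`, `group` ("cryptic"/"canonical"),
#'   `expr`.
#' @export
gen_nucleus_expression <- function(n_cryptic = 87, n_canonical = 377,
                                   mean_cryptic = 1.65,
                                   mean_canonical = 1.35, sd = 0.8,
                                   seed = 1) {
  stopifnot(n_cryptic >= 1, n_canonical >= 1, sd >= 0)
  with_seed(stream_seed(seed, "nuclei"), {
    data.frame(
      nucleus_id = seq_len(n_cryptic + n_canonical),
      group = rep(c("cryptic", "canonical"), c(n_cryptic, n_canonical)),
      expr = c(stats::rnorm(n_cryptic, mean_cryptic, sd),
               stats::rnorm(n_canonical, mean_canonical, sd)),
      stringsAsFactors = FALSE
    )
  })
}
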