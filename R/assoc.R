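# Pathway-level correlations between transcript abundance and the CGE
# metric, restricted to the PLSR-selected (CGE-associated) genes.

.expr_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    genes <- expr[["gene"]]
    m <- as.matrix(expr[setdiff(names(expr), "gene")])
    rownames(m) <- genes
    m
  } else {
    as.matrix(expr)
  }
}

#' Pearson correlations between pathway transcript sums and log CGE
#'
#' For each curated pathway, sums the normalized transcript abundances of
#' its CGE-associated genes within each sample and correlates the sum with
#' the log-transformed CGE metric, reporting the Pearson coefficient, a
#' two-sided p-value with Benjamini-Hochberg correction across pathways,
#' and the linear regression fit used for plotting.
#'
#' @param expr A gene-by-sample tibble (a `gene` column plus one column per
#'   sample) or matrix of normalized transcript abundances.
#' @param cge Named numeric vector of CGE values (names = sample ids), or a
#'   tibble with `sample_id` and `cge`. Samples with non-positive CGE are
#'   dropped (log undefined); drops are reported.
#' @param pathways A tibble with columns `gene` and `pathway` mapping gene
#'   ids to named pathways. A synthetic default list matching the simulated
#'   gene ids ships at `system.file("extdata", "pathways_synthetic.tsv",
#'   package = "qsipcge")`; supply a curated list for real data.
#' @param genes Optional character vector restricting the sums to these
#'   genes (typically the PLSR-selected set); `NULL` uses all pathway genes.
#' @return A tibble per pathway: `pathway`, `n_genes`, `r`, `p_value`,
#'   `p_fdr`, `slope`, `intercept`. Pathways with no usable genes are
#'   skipped with a warning.
#' @export
pathway_correlations <- function(expr, cge, pathways, genes = NULL) {
  m <- .expr_matrix(expr)
  cge_vec <- .cge_vector(cge, colnames(m))
  y <- log(cge_vec$cge)
  m <- m[, cge_vec$sample, drop = FALSE]

  out <- map(split(pathways$gene, pathways$pathway), function(gset) {
    if (!is.null(genes)) gset <- intersect(gset, genes)
    gset <- intersect(gset, rownames(m))
    if (length(gset) == 0) {
      return(NULL)
    }
    s <- colSums(m[gset, , drop = FALSE])
    if (sd(s) == 0) {
      return(NULL)
    }
    ct <- cor.test(s, y)
    fit <- lm(y ~ s)
    tibble(n_genes = length(gset), r = unname(ct$estimate),
           p_value = ct$p.value,
           slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  })
  skipped <- names(out)[vapply(out, is.null, logical(1))]
  if (length(skipped) > 0) {
    warn(paste("pathways skipped (no usable genes):",
               paste(skipped, collapse = ", ")))
  }
  res <- imap(out, ~ if (!is.null(.x)) mutate(.x, pathway = .y)) |>
    list_rbind()
  if (nrow(res) == 0) abort("no pathway had usable genes")
  res |>
    mutate(p_fdr = p.adjust(.data$p_value, "BH")) |>
    select("pathway", "n_genes", "r", "p_value", "p_fdr", "slope",
           "intercept")
}

.cge_vector <- function(cge, sample_ids) {
  if (is.data.frame(cge)) {
    v <- setNames(cge$cge, cge$sample_id)
  } else {
    v <- cge
  }
  common <- intersect(sample_ids, names(v))
  if (length(common) < 3) abort("fewer than 3 samples shared with CGE table")
  v <- v[common]
  bad <- !is.finite(v) | v <= 0
  if (any(bad)) {
    inform(sprintf("%d sample(s) dropped: CGE not positive", sum(bad)))
  }
  list(sample = common[!bad], cge = unname(v[!bad]))
}

#' Correlation of a transcript-abundance ratio with log CGE
#'
#' Sums the numerator and denominator gene sets per sample (for example,
#' biosynthesis versus energy-production transcripts), takes their ratio,
#' and correlates it with the log CGE metric. Samples with a zero
#' denominator are dropped with a warning.
#'
#' @inheritParams pathway_correlations
#' @param numerator_genes,denominator_genes Character vectors of gene ids.
#' @return A one-row tibble `r`, `p_value`, `slope`, `intercept`,
#'   `n_samples`.
#' @export
ratio_correlation <- function(expr, cge, numerator_genes,
                              denominator_genes) {
  m <- .expr_matrix(expr)
  cge_vec <- .cge_vector(cge, colnames(m))
  m <- m[, cge_vec$sample, drop = FALSE]
  num <- colSums(m[intersect(numerator_genes, rownames(m)), , drop = FALSE])
  den <- colSums(m[intersect(denominator_genes, rownames(m)), ,
                   drop = FALSE])
  ok <- den != 0
  if (any(!ok)) {
    warn(sprintf("%d sample(s) dropped: zero denominator", sum(!ok)))
  }
  ratio <- num[ok] / den[ok]
  y <- log(cge_vec$cge[ok])
  ct <- cor.test(ratio, y)
  fit <- lm(y ~ ratio)
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_samples = sum(ok))
}

#' Associate gene expression with the CGE metric via PLSR
#'
#' Convenience wrapper for the full association flow: builds the
#' sample-by-gene predictor matrix from a gene-by-sample expression table,
#' matches samples to CGE values (excluding non-positive CGE), fits the PLS
#' regression of log CGE on expression, and returns the VIP-ranked gene
#' table with the top decile flagged.
#'
#' @inheritParams pathway_correlations
#' @param ncomp,scale,max_ncomp Passed to [plsr_fit()].
#' @param fraction Passed to [select_top()].
#' @return A list: `model` (the `pls_cge` fit), `associations` (the
#'   [select_top()] tibble), `samples_used`.
#' @export
cge_association <- function(expr, cge, ncomp = NULL, scale = TRUE,
                            max_ncomp = 10, fraction = 0.10) {
  m <- .expr_matrix(expr)
  cge_vec <- .cge_vector(cge, colnames(m))
  x <- t(m[, cge_vec$sample, drop = FALSE])
  model <- plsr_fit(x, log(cge_vec$cge), ncomp = ncomp, scale = scale,
                    max_ncomp = max_ncomp)
  list(model = model, associations = select_top(model, fraction),
       samples_used = cge_vec$sample)
}
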