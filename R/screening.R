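#' Synthetic phenotype and expression data for screening experiments
#'
#' Generates a cohort shaped like a brain-volume expression study: a
#' phenotype table (scaled hippocampus-volume-like outcome with age,
#' gender and education covariates), an expression matrix of i.i.d.
#' standard-normal gene values, and ground-truth causal labels. A handful
#' of causal genes act on the phenotype through linear, quadratic or
#' cosine effect functions; the remaining genes are pure noise. Effect
#' functions are applied to the probability-integral transform
#' `u = 2*pnorm(g) - 1` of the standardized expression value `g`, so that
#' `u` is Uniform`[-1, 1]` and the effect shapes and sizes match the
#' multiple-signal simulation design exactly.
#' Two extra standard-normal `background` covariates with no phenotype
#' effect are returned for use as the conditioning set of per-gene
#' goodness-of-fit tests.
#'
#' @param n_samples Number of individuals (default 464).
#' @param n_genes Number of genes (default 2000).
#' @param causal A data frame with columns `gene` (1-based index),
#'   `effect` (`"linear"`, `"quadratic"` or `"cosine"`) and `size`
#'   (multiplier); default: genes 1-3 with the three effect shapes at the
#'   simulation-design sizes (1, 2, 1).
#' @param confounding If `TRUE` (default) the phenotype includes linear
#'   age, gender and education effects.
#' @param noise_sd Phenotype noise standard deviation (default 0.5).
#' @param seed Integer seed.
#' @return A list with `pheno` (data frame: `sample_id`, `phenotype`,
#'   `age`, `gender`, `education`), `expr` (samples x genes matrix, gene
#'   identifiers as column names, sample identifiers as row names),
#'   `background` (samples x 2 matrix) and `truth` (logical vector over
#'   genes).
#' @export
synth_expression <- function(n_samples = 464L, n_genes = 2000L,
                             causal = default_causal_spec(),
                             confounding = TRUE, noise_sd = 0.5,
                             seed = 1L) {
  stopifnot(n_samples >= 10, n_genes >= 1)
  if (nrow(causal) > 0 &&
      (any(causal$gene < 1L) || any(causal$gene > n_genes)))
    stop("causal gene indices must lie in 1..n_genes", call. = FALSE)
  if (!all(causal$effect %in% c("linear", "quadratic", "cosine")))
    stop("unknown effect function in `causal`", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n_samples))
  genes <- sprintf("G%04d", seq_len(n_genes))
  expr <- matrix(rnorm(n_samples * n_genes), n_samples, n_genes,
                 dimnames = list(ids, genes))
  age <- rnorm(n_samples, 75, 7)
  gender <- stats::rbinom(n_samples, 1L, 0.5)
  education <- sample(8:20, n_samples, replace = TRUE)
  signal <- rep(0, n_samples)
  for (i in seq_len(nrow(causal))) {
    u <- 2 * pnorm(expr[, causal$gene[i]]) - 1  # Uniform[-1, 1]
    signal <- signal + causal$size[i] * switch(causal$effect[i],
      linear = u, quadratic = u^2, cosine = cos(2 * pi * u))
  }
  covar <- if (confounding) {
    -0.03 * (age - 75) + 0.2 * gender + 0.05 * (education - 14)
  } else 0
  phenotype <- covar + signal + rnorm(n_samples, 0, noise_sd)
  truth <- logical(n_genes)
  truth[causal$gene] <- TRUE
  names(truth) <- genes
  list(
    pheno = data.frame(sample_id = ids, phenotype = phenotype, age = age,
                       gender = gender, education = education,
                       stringsAsFactors = FALSE),
    expr = expr,
    background = matrix(rnorm(2 * n_samples), n_samples, 2,
                        dimnames = list(ids, c("bg1", "bg2"))),
    truth = truth
  )
}

#' @rdname synth_expression
#' @export
default_causal_spec <- function() {
  data.frame(gene = 1:3,
             effect = c("linear", "quadratic", "cosine"),
             size = c(1, 2, 1), stringsAsFactors = FALSE)
}

#' Covariate-adjust a phenotype
#'
#' Ordinary least-squares residuals of the phenotype on intercept, age,
#' gender and education. The residual vector is the response used for the
#' per-gene tests; it has mean zero and is orthogonal to each covariate.
#'
#' @param pheno A data frame with columns `phenotype`, `age`, `gender`,
#'   `education` (as produced by [synth_expression()] or read with
#'   [load_tabular()]).
#' @return Numeric residual vector, one entry per row of `pheno`.
#' @export
adjust_phenotype <- function(pheno) {
  need <- c("phenotype", "age", "gender", "education")
  miss <- setdiff(need, names(pheno))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- !stats::complete.cases(pheno[, need])
  if (any(bad))
    stop("missing covariate or phenotype values in rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  fit <- stats::lm(phenotype ~ age + gender + education, data = pheno)
  if (anyNA(coef(fit)))
    stop("covariate design is rank deficient", call. = FALSE)
  unname(resid(fit))
}

#' Screen genes for association with an adjusted phenotype
#'
#' Tests every gene in turn for association with the covariate-adjusted
#' phenotype residual, using either the linear-model t-test or the
#' goodness-of-fit network test, and ranks genes by ascending p-value
#' (ties broken by gene identifier). For the network test each gene is
#' tested marginally: the covariate matrix is the gene plus a small
#' conditioning `background` set, and the null model uses the background
#' only. A per-gene failure (e.g. a degenerate constant gene) is logged,
#' assigned a missing p-value and ranked last.
#'
#' @param expr Samples x genes expression matrix with gene identifiers as
#'   column names.
#' @param residual Adjusted phenotype residual vector (see
#'   [adjust_phenotype()]), aligned with the rows of `expr`.
#' @param method `"linear"`, `"shallow"`, `"deep1"` or `"deep2"`.
#' @param background Samples x k matrix of conditioning covariates;
#'   required for the network methods (the null model must retain at least
#'   one input).
#' @param gamma Split proportion for the network test (default 0.5).
#' @param control A [relu_control()] template; the per-gene seed is derived
#'   from its seed.
#' @return An object of class `"screening_result"`: a data frame with
#'   columns `gene`, `statistic`, `p_value`, `rank`, ordered by rank, with
#'   the method recorded in `attr(, "method")`.
#' @export
screen_genes <- function(expr, residual,
                         method = c("linear", "shallow", "deep1", "deep2"),
                         background = NULL, gamma = 0.5,
                         control = relu_control()) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (nrow(expr) != length(residual))
    stop("rows(expr) must match length(residual)", call. = FALSE)
  if (nrow(expr) < max(20L, control$num_batches))
    stop("need at least max(20, num_batches) samples", call. = FALSE)
  if (method != "linear") {
    if (is.null(background))
      stop("the network methods need a `background` conditioning matrix: ",
           "the null model must keep at least one covariate", call. = FALSE)
    background <- as.matrix(background)
    if (nrow(background) != nrow(expr))
      stop("`background` rows must match `expr`", call. = FALSE)
  }
  genes <- colnames(expr) %||% sprintf("G%04d", seq_len(ncol(expr)))

  stat <- pval <- rep(NA_real_, ncol(expr))
  for (g in seq_len(ncol(expr))) {
    res <- tryCatch({
      if (method == "linear") {
        xg <- if (is.null(background)) expr[, g, drop = FALSE]
              else cbind(expr[, g, drop = FALSE], background)
        p <- linear_t_test(xg, residual, 1L)
        list(stat = NA_real_, p = p)
      } else {
        ctl <- control
        ctl$seed <- restart_seed(control$seed, 97L * g)
        t <- gof_test(cbind(gene = expr[, g], background), residual,
                      S = 1L, kind = method, gamma = gamma, control = ctl)
        list(stat = unname(t$statistic), p = t$p.value)
      }
    }, error = function(e) {
      message("gene ", genes[g], " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      stat[g] <- res$stat
      pval[g] <- res$p
    }
  }
  # rank ascending in p; NA last; ties broken by gene identifier
  ord <- order(pval, genes, na.last = TRUE)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  out <- data.frame(gene = genes, statistic = stat, p_value = pval,
                    rank = rank, stringsAsFactors = FALSE)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "gamma") <- gamma
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Top-ranked genes of a screening result
#'
#' @param result A [screen_genes()] result.
#' @param k Number of genes to return (`0 <= k <=` number of genes).
#' @return Character vector of the first `k` gene identifiers by rank.
#' @export
top_k <- function(result, k) {
  stopifnot(inherits(result, "screening_result"))
  k <- as.integer(k)
  if (k < 0L || k > nrow(result))
    stop("`k` must be in 0..", nrow(result), call. = FALSE)
  result$gene[seq_len(k)]
}
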