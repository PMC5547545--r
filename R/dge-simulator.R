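## Negative-binomial count simulator for a 2x2 treatment x time design:
## per-gene (mean, dispersion) pairs sampled from a parametric mean-variance
## trend, truth categories (constant fold change, single-timepoint DE,
## differential interaction) and NB counts with log-normal library sizes.

#' Mean-dispersion model for NB count simulation
#'
#' Joint sampler for per-gene baseline means mu_g (log-normal) and NB
#' dispersions phi_g (variance = mu + phi * mu^2) on a decreasing trend
#' phi = a0 + a1 / mu, with multiplicative log-normal noise around the
#' trend. This is a parametric stand-in for empirically estimated
#' mean-dispersion pairs; an empirical table of (mu, phi) pairs may be
#' supplied instead and is then resampled jointly.
#'
#' @param meanlog,sdlog parameters of the log-normal law for mu_g; defaults
#'   give a median around 50 counts with a long right tail.
#' @param a0 asymptotic dispersion at high expression (squared biological
#'   coefficient of variation); default 0.05.
#' @param a1 low-count dispersion inflation; default 3.
#' @param phi_sdlog log-scale standard deviation of the noise around the
#'   trend; 0 puts every gene exactly on the trend.
#' @param empirical optional data.frame with columns `mu`, `phi` to resample
#'   from instead of the parametric model.
#' @return an object of class `mean_dispersion_model`.
#' @export
mean_dispersion_model <- function(meanlog = log(50), sdlog = 1.5,
                                  a0 = 0.05, a1 = 3, phi_sdlog = 0.4,
                                  empirical = NULL) {
  if (!is.null(empirical)) {
    if (!all(c("mu", "phi") %in% names(empirical)) ||
        any(empirical$mu <= 0) || any(empirical$phi < 0)) {
      stop("empirical must have columns mu > 0 and phi >= 0")
    }
  } else if (sdlog < 0 || a0 < 0 || a1 < 0 || phi_sdlog < 0) {
    stop("model parameters must be non-negative")
  }
  structure(list(meanlog = meanlog, sdlog = sdlog, a0 = a0, a1 = a1,
                 phi_sdlog = phi_sdlog, empirical = empirical),
            class = "mean_dispersion_model")
}

#' Sample per-gene means and dispersions
#'
#' @param n number of genes.
#' @param model a [mean_dispersion_model()].
#' @param seed integer seed; draws are deterministic given the seed.
#' @return data.frame with columns `mu`, `phi`.
#' @export
sample_mean_dispersion <- function(n, model = mean_dispersion_model(),
                                   seed = 1L) {
  stopifnot(inherits(model, "mean_dispersion_model"), n >= 1)
  set.seed(seed)
  if (!is.null(model$empirical)) {
    idx <- sample.int(nrow(model$empirical), n, replace = TRUE)
    return(data.frame(mu = model$empirical$mu[idx],
                      phi = model$empirical$phi[idx]))
  }
  mu <- stats::rlnorm(n, meanlog = model$meanlog, sdlog = model$sdlog)
  trend <- model$a0 + model$a1 / mu
  phi <- trend * stats::rlnorm(n, meanlog = 0, sdlog = model$phi_sdlog)
  data.frame(mu = mu, phi = phi)
}

#' Configuration for the 2x2 DGE simulation
#'
#' Defaults reproduce the factorial simulation design: 13,000 genes with
#' 2000 genes changing by a constant fold between treatment and control at
#' both timepoints, 1000 genes with DE only at timepoint 1, 1000 only at
#' timepoint 2, and 1000 genes DE at both timepoints with a different fold
#' change (a true treatment x time interaction); all fold changes 3 or 1/3,
#' directions balanced within every category.
#'
#' @param n_genes total genes; default 13000.
#' @param n_per_group biological replicates per treatment x time cell;
#'   default 5.
#' @param n_constant,n_t1,n_t2,n_interaction category sizes; must sum to at
#'   most `n_genes`.
#' @param fold_change fold-change magnitude (> 1); default 3.
#' @param lib_sdlog log-scale sd of the log-normal library-size factors
#'   (centred at 1); default 0.25.
#' @param seed integer seed, mandatory for any simulation.
#' @return an object of class `dge_config`.
#' @export
dge_config <- function(n_genes = 13000, n_per_group = 5,
                       n_constant = 2000, n_t1 = 1000, n_t2 = 1000,
                       n_interaction = 1000, fold_change = 3,
                       lib_sdlog = 0.25, seed = 1L) {
  sizes <- c(n_constant, n_t1, n_t2, n_interaction)
  stopifnot(n_genes >= 1, n_per_group >= 2, all(sizes >= 0),
            fold_change > 1, lib_sdlog >= 0)
  if (sum(sizes) > n_genes) stop("category sizes exceed n_genes")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 n_constant = as.integer(n_constant),
                 n_t1 = as.integer(n_t1), n_t2 = as.integer(n_t2),
                 n_interaction = as.integer(n_interaction),
                 fold_change = fold_change, lib_sdlog = lib_sdlog,
                 seed = as.integer(seed)),
            class = "dge_config")
}

## Balanced direction assignment: exactly ceiling(n/2) up, floor(n/2) down.
.balanced_signs <- function(n) {
  if (n == 0L) return(logical(0))
  rep(c(TRUE, FALSE), length.out = n)  # ties toward up
}

#' Assign DGE ground truth
#'
#' Partitions genes into the configured categories (no overlap), assigns
#' fold changes at the two timepoints with balanced directions, and derives
#' the per-gene null flags. The logical closure holds by construction:
#' single-timepoint DE implies a non-null interaction; a constant fold
#' change implies a null interaction; the screening null is the conjunction
#' of the three hypothesis nulls.
#'
#' @param config a [dge_config()].
#' @return data.frame with one row per gene: `gene`, `category`, `fc_t1`,
#'   `fc_t2` (treatment/control mean ratio at each timepoint), `null_t1`,
#'   `null_t2`, `null_interaction`, `null_screening`.
#' @export
assign_dge_truth <- function(config) {
  stopifnot(inherits(config, "dge_config"))
  set.seed(config$seed)
  n <- config$n_genes
  fc <- config$fold_change
  gene <- sprintf("gene%05d", seq_len(n))
  category <- rep("null", n)
  pool <- sample.int(n)  # random, seed-determined category placement
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  idx_const <- take(config$n_constant)
  idx_t1 <- take(config$n_t1)
  idx_t2 <- take(config$n_t2)
  idx_int <- take(config$n_interaction)
  category[idx_const] <- "constant"
  category[idx_t1] <- "t1_only"
  category[idx_t2] <- "t2_only"
  category[idx_int] <- "interaction_both"

  fc_t1 <- rep(1, n)
  fc_t2 <- rep(1, n)
  up <- .balanced_signs(length(idx_const))
  fc_t1[idx_const] <- ifelse(up, fc, 1 / fc)
  fc_t2[idx_const] <- fc_t1[idx_const]
  up <- .balanced_signs(length(idx_t1))
  fc_t1[idx_t1] <- ifelse(up, fc, 1 / fc)
  up <- .balanced_signs(length(idx_t2))
  fc_t2[idx_t2] <- ifelse(up, fc, 1 / fc)
  ## interaction-both genes: distinct members of {fc, 1/fc} at the two
  ## timepoints, ordering balanced
  up <- .balanced_signs(length(idx_int))
  fc_t1[idx_int] <- ifelse(up, fc, 1 / fc)
  fc_t2[idx_int] <- ifelse(up, 1 / fc, fc)

  null_t1 <- fc_t1 == 1
  null_t2 <- fc_t2 == 1
  null_interaction <- fc_t1 == fc_t2
  data.frame(gene = gene, category = category,
             fc_t1 = fc_t1, fc_t2 = fc_t2,
             null_t1 = null_t1, null_t2 = null_t2,
             null_interaction = null_interaction,
             null_screening = null_t1 & null_t2 & null_interaction,
             stringsAsFactors = FALSE)
}

#' Long-format hypothesis truth for a DGE truth table
#'
#' Expands the per-gene truth into (gene, hypothesis, is_null) records for
#' the hypotheses `t1`, `t2`, `interaction`, as consumed by
#' [gene_level_fdp()] and the evaluation module.
#'
#' @param truth output of [assign_dge_truth()].
#' @return data.frame with columns `gene`, `hypothesis`, `is_null`.
#' @export
dge_truth_long <- function(truth) {
  stopifnot(all(c("gene", "null_t1", "null_t2", "null_interaction")
                %in% names(truth)))
  data.frame(
    gene = rep(truth$gene, times = 3L),
    hypothesis = rep(c("t1", "t2", "interaction"), each = nrow(truth)),
    is_null = c(truth$null_t1, truth$null_t2, truth$null_interaction),
    stringsAsFactors = FALSE
  )
}

#' Simulate hypothesis-level p-values with the DGE truth structure
#'
#' A p-value-level companion to [simulate_dge_counts()]: instead of counts
#' and a fitting engine, it draws the per-hypothesis p-values directly -
#' U(0,1) for true nulls (exactly valid by construction) and a
#' stochastically smaller Beta(`beta_shape`, 1) for false nulls - together
#' with an independent screening p-value per gene (U(0,1) for fully-null
#' genes, Beta(`beta_shape`, 1) otherwise). Useful for validating OFDR
#' control of the testing procedure itself, free of any miscalibration a
#' count-level test engine might introduce.
#'
#' @param config a [dge_config()]; only the truth structure and seed are
#'   used.
#' @param beta_shape first shape parameter of the Beta(a, 1) alternative
#'   law; smaller = stronger signal. Default 0.1.
#' @return list with `table` (gene, hypothesis, p), `screening` (gene, p),
#'   `truth` and `truth_long`.
#' @export
simulate_dge_pvalues <- function(config, beta_shape = 0.1) {
  stopifnot(inherits(config, "dge_config"), beta_shape > 0)
  truth <- assign_dge_truth(config)          # seeds with config$seed
  truth_long <- dge_truth_long(truth)
  set.seed(config$seed + 1L)
  n <- nrow(truth_long)
  p <- numeric(n)
  p[truth_long$is_null] <- stats::runif(sum(truth_long$is_null))
  p[!truth_long$is_null] <- stats::rbeta(sum(!truth_long$is_null),
                                         beta_shape, 1)
  p_scr <- ifelse(truth$null_screening,
                  stats::runif(nrow(truth)),
                  stats::rbeta(nrow(truth), beta_shape, 1))
  list(table = data.frame(gene = truth_long$gene,
                          hypothesis = truth_long$hypothesis, p = p,
                          stringsAsFactors = FALSE),
       screening = data.frame(gene = truth$gene, p = p_scr,
                              stringsAsFactors = FALSE),
       truth = truth, truth_long = truth_long)
}

#' Simulate NB counts for the 2x2 DGE design
#'
#' Counts are drawn from a negative binomial with mean
#' library factor x mu_g x condition multiplier and dispersion phi_g
#' (variance mu + phi mu^2; phi = 0 reduces to Poisson). Gene
#' characteristics (mu_g, phi_g) are shared across timepoints, linking each
#' gene over the time course. Control samples have multiplier 1; treated
#' samples use the truth fold change of their timepoint.
#'
#' @param config a [dge_config()].
#' @param model a [mean_dispersion_model()].
#' @return list with `counts` (genes x samples integer matrix), `design`
#'   (data.frame: sample, treatment, time, replicate, lib_factor), `truth`
#'   (per-gene truth from [assign_dge_truth()]), `truth_long` (hypothesis
#'   truth), and `params` (per-gene mu, phi).
#' @export
simulate_dge_counts <- function(config, model = mean_dispersion_model()) {
  stopifnot(inherits(config, "dge_config"))
  truth <- assign_dge_truth(config)          # seeds with config$seed
  params <- sample_mean_dispersion(config$n_genes, model,
                                   seed = config$seed + 1L)
  set.seed(config$seed + 2L)
  n_rep <- config$n_per_group
  design <- expand.grid(replicate = seq_len(n_rep),
                        treatment = c("control", "treated"),
                        time = c("t1", "t2"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("treatment", "time", "replicate")]
  design$sample <- sprintf("%s_%s_rep%d", design$treatment, design$time,
                           design$replicate)
  n_samp <- nrow(design)
  design$lib_factor <- stats::rlnorm(n_samp, meanlog = 0,
                                     sdlog = config$lib_sdlog)
  if (any(design$lib_factor <= 0)) stop("library factors must be positive")

  mult <- matrix(1, nrow = config$n_genes, ncol = n_samp)
  treated <- design$treatment == "treated"
  mult[, treated & design$time == "t1"] <- truth$fc_t1
  mult[, treated & design$time == "t2"] <- truth$fc_t2

  mu_mat <- outer(params$mu, design$lib_factor) * mult
  size <- 1 / params$phi  # phi = 0 -> size = Inf -> Poisson limit
  counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                  size = rep(size, times = n_samp)),
                   nrow = config$n_genes,
                   dimnames = list(truth$gene, design$sample))
  list(counts = counts, design = design, truth = truth,
       truth_long = dge_truth_long(truth), params = params)
}
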