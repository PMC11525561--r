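# normalize input: named list of numeric vectors, or long data.frame with
# condition_label/value columns
as_group_list <- function(groups, label_col = "condition_label",
                          value_col = "value") {
  if (is.data.frame(groups)) {
    if (!all(c(label_col, value_col) %in% names(groups)))
      stop("data.frame input needs columns '", label_col, "' and '", value_col, "'")
    groups <- split(groups[[value_col]], groups[[label_col]])
  }
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list or a long data.frame")
  lapply(groups, as.numeric)
}

#' One-way analysis of variance
#'
#' Standard between/within sums-of-squares decomposition with the p-value
#' from the F distribution.
#'
#' @param groups named list of numeric vectors, or a long data.frame with
#'   `condition_label` and `value` columns. Every group needs >= 2 values.
#' @return list with `F`, `p`, `df_between`, `df_within`, `ms_within`.
#' @export
anova_oneway <- function(groups) {
  g <- as_group_list(groups)
  if (length(g) < 2L) stop("need >= 2 groups")
  n_i <- lengths(g)
  if (any(n_i < 2L)) stop("every group needs >= 2 values")
  values <- unlist(g, use.names = FALSE)
  labels <- factor(rep(names(g), n_i))
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1L)))
  if (ss_within == 0) stop("zero within-group variance in all groups; F undefined")
  fit <- stats::lm(values ~ labels)
  tab <- stats::anova(fit)
  list(F = tab$`F value`[1L], p = tab$`Pr(>F)`[1L],
       df_between = tab$Df[1L], df_within = tab$Df[2L],
       ms_within = tab$`Mean Sq`[2L])
}

#' Dunnett many-to-one comparisons against a control
#'
#' Two-tailed single-step Dunnett test: every treatment group is compared
#' with the designated control using t statistics on the pooled
#' within-group mean square, and p-values are adjusted over the whole
#' family via the equicorrelated multivariate t distribution (correlation
#' lambda_i * lambda_j with lambda_i = sqrt(n_i / (n_i + n_c)); 0.5 for
#' balanced designs). The multivariate t probability is evaluated by
#' randomized quasi-Monte-Carlo integration under a fixed internal seed, so
#' results are reproducible to the integration tolerance (about 5e-4). With
#' a single treatment group the adjusted p is the exact pooled two-sample
#' two-sided t p-value.
#'
#' @param groups named list of numeric vectors (>= 2 values each) or long
#'   data.frame with `condition_label`/`value` columns.
#' @param control_label name of the control group.
#' @param alpha familywise level used only for the `significant` flag
#'   (default 0.05).
#' @param mc_seed integer seed for the multivariate t integration.
#' @return data.frame, one row per treatment group: `comparison`,
#'   `mean_difference`, `t_statistic`, `p_unadjusted`, `adjusted_p`,
#'   `stars`, `significant`.
#' @export
dunnett_test <- function(groups, control_label, alpha = 0.05,
                         mc_seed = 20241030L) {
  g <- as_group_list(groups)
  if (!control_label %in% names(g))
    stop("control group '", control_label, "' not found among: ",
         paste(names(g), collapse = ", "))
  if (length(g) < 2L) stop("need the control and >= 1 treatment group")
  n_i <- lengths(g)
  if (any(n_i < 2L)) stop("every group needs >= 2 values for variance estimation")

  vars <- vapply(g, stats::var, numeric(1L))
  if (all(vars == 0)) stop("zero within-group variance in all groups")
  pos <- vars[vars > 0]
  if (length(pos) > 1L && max(pos) / min(pos) > 10)
    warning("group variances differ by more than 10-fold; pooled-variance Dunnett may be unreliable")

  means <- vapply(g, mean, numeric(1L))
  N <- sum(n_i); k_all <- length(g)
  msw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1L))) / (N - k_all)
  df <- N - k_all

  treat <- setdiff(names(g), control_label)
  nc <- n_i[[control_label]]
  tstat <- vapply(treat, function(lab) {
    (means[[lab]] - means[[control_label]]) /
      sqrt(msw * (1 / n_i[[lab]] + 1 / nc))
  }, numeric(1L))
  p_un <- 2 * stats::pt(-abs(tstat), df = df)

  k <- length(treat)
  if (k == 1L) {
    p_adj <- p_un
  } else {
    lambda <- sqrt(n_i[treat] / (n_i[treat] + nc))
    corr <- outer(lambda, lambda)
    diag(corr) <- 1
    p_adj <- vapply(abs(tstat), function(tt) {
      pr <- with_seed(mc_seed, mvtnorm::pmvt(
        lower = rep(-tt, k), upper = rep(tt, k),
        corr = corr, df = df, type = "shifted"))
      1 - as.numeric(pr)
    }, numeric(1L))
    p_adj <- pmin(1, pmax(p_adj, p_un))  # family adjustment never helps
  }

  data.frame(
    comparison = paste(treat, "vs", control_label),
    group = treat,
    mean_difference = unname(means[treat] - means[[control_label]]),
    t_statistic = unname(tstat),
    p_unadjusted = unname(p_un),
    adjusted_p = unname(p_adj),
    stars = significance_stars(unname(p_adj)),
    significant = unname(p_adj < alpha),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# evaluate expr under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Significance stars for reported p-values
#'
#' Strict-inequality thresholds: `***` p < 0.001, `**` p < 0.01, `*`
#' p < 0.05, otherwise `ns` (so p = 0.05 exactly is `ns`).
#'
#' @param p probability (vectorized), each in \[0, 1\].
#' @return character vector of `ns`, `*`, `**`, `***`.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Per-stratum ANOVA + Dunnett over a long table
#'
#' Runs [anova_oneway()] and [dunnett_test()] independently within each
#' stratum (typically each substrate concentration point, mirroring the
#' per-concentration testing of plate assays).
#'
#' @param data long data.frame with `condition_label`, `value` and the
#'   stratum column.
#' @param control_label control condition.
#' @param stratum name of the stratum column (default `"substrate_conc"`).
#' @param alpha familywise level (default 0.05).
#' @return data.frame of Dunnett rows with a leading stratum column and the
#'   per-stratum ANOVA F and p attached.
#' @export
dunnett_by_stratum <- function(data, control_label,
                               stratum = "substrate_conc", alpha = 0.05) {
  stopifnot(is.data.frame(data), stratum %in% names(data))
  parts <- split(data, data[[stratum]])
  out <- lapply(names(parts), function(sv) {
    d <- parts[[sv]]
    an <- anova_oneway(d)
    dt <- dunnett_test(d, control_label, alpha = alpha)
    dt[[stratum]] <- as.numeric(sv)
    dt$anova_F <- an$F
    dt$anova_p <- an$p
    dt
  })
  res <- do.call(rbind, out)
  res[, c(stratum, setdiff(names(res), stratum))]
}
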