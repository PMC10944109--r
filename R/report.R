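#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' The group-comparison procedure used for all strain/condition panels:
#' an ordinary one-way ANOVA (omnibus F and p) followed by Dunnett's test
#' of every group against the designated control, via the multivariate-t
#' distribution of the simultaneous contrasts. The multivariate-t tail
#' probabilities are evaluated by randomized quasi-Monte Carlo, so a seed
#' fixes the adjusted p values; unadjusted per-comparison p values are
#' reported alongside and are never larger than the adjusted ones.
#'
#' @param values numeric response.
#' @param groups group labels, same length.
#' @param control name of the control group.
#' @param seed seed for the multivariate-t evaluation.
#' @return list of class `group_comparison`: `anova_F`, `anova_p`,
#'   `groups` (data frame label/n/mean/sd), `comparisons` (data frame
#'   group, estimate, p_unadjusted, p_adjusted), `control`.
#' @export
anova_dunnett <- function(values, groups, control, seed = 1L) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group not present: ", control)
  labs <- unique(groups)
  if (length(labs) < 2L) stop("need at least 2 groups")
  tab <- table(groups)
  if (any(tab < 2L)) stop("every group needs n >= 2")
  df <- data.frame(value = values,
                   group = stats::relevel(factor(groups), ref = control))
  if (stats::var(values) == 0)
    stop("degenerate data: zero variance overall")
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  adj <- withr::with_seed(seed, summary(glt)$test)
  unadj <- summary(glt, test = multcomp::adjusted("none"))$test
  comp_names <- sub(" - .*$", "", names(adj$coefficients))
  per_group <- do.call(rbind, lapply(labs, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  structure(list(
    anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
    groups = per_group,
    comparisons = data.frame(group = comp_names,
                             estimate = unname(adj$coefficients),
                             p_unadjusted = unname(unadj$pvalues),
                             p_adjusted = unname(adj$pvalues)),
    control = control), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA F = %.3g, p = %.3g; control = %s\n",
              x$anova_F, x$anova_p, x$control))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Percent decrease of a mean relative to a reference mean
#'
#' `100 * (reference - value) / reference`; e.g. an average maximum of 683
#' molecules against a control of 783 is a 13% decrease (to the nearest
#' percent).
#'
#' @param value,reference the two means (reference > 0).
#' @export
percent_decrease <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be > 0")
  100 * (reference - value) / reference
}

#' Assemble the run report
#'
#' Writes every supplied stage output as a CSV under `out_dir` and a JSON
#' manifest recording which stages were present, which were absent, the
#' seed and a hash of the configuration. Given identical inputs the
#' outputs are byte-identical.
#'
#' @param outputs named list of data frames (e.g. `strain_summary`,
#'   `patch_metrics`, `bead_velocity`, `angular_profile`, `bundles`,
#'   `binding_fits`, `titration_fits`). `NULL` entries are recorded as
#'   absent.
#' @param out_dir output directory (created if needed).
#' @param config optional configuration list, hashed into the manifest.
#' @param seed seed recorded in the manifest.
#' @return path of the manifest, invisibly.
#' @export
build_report <- function(outputs, out_dir, config = NULL, seed = NA) {
  stopifnot(is.list(outputs), !is.null(names(outputs)),
            all(nzchar(names(outputs))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  present <- character(0); absent <- character(0)
  for (nm in names(outputs)) {
    tabl <- outputs[[nm]]
    if (is.null(tabl)) {
      absent <- c(absent, nm)
      next
    }
    if (!is.data.frame(tabl))
      stop("stage output is not a table: ", nm)
    if (!nrow(tabl)) stop("stage output is empty: ", nm)
    write_table(tabl, file.path(out_dir, paste0(nm, ".csv")))
    present <- c(present, nm)
  }
  manifest <- list(
    tables = as.list(present),
    absent = as.list(absent),
    seed = seed,
    config_hash = if (is.null(config)) NA else
      config_hash(config))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Small stable hash of a configuration list (sum over serialized bytes).
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2L)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 2^31)
}
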