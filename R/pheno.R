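## Multi-environment phenotype handling: replicate means, least-squares
## means across environments, between-location correlations, trait summary.

check_records <- function(records) {
  need <- c("genotype", "environment", "value")
  if (!all(need %in% names(records)))
    stop("phenotype records need columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(records$value)))
    stop("phenotype values must be finite")
  records$genotype <- as.character(records$genotype)
  records$environment <- as.character(records$environment)
  records
}

#' Average replicates within genotype-by-environment cells
#'
#' Collapses replicated plot records to one mean record per observed
#' genotype x environment cell, the usual first step before computing
#' least-squares means from a two-way additive model.
#'
#' @param records Data frame with columns `genotype`, `environment`, `value`
#'   (and optionally `replicate`, which is dropped).
#' @return Data frame with one row per genotype x environment cell.
#' @export
replicate_means <- function(records) {
  records <- check_records(records)
  agg <- stats::aggregate(value ~ genotype + environment, data = records,
                          FUN = mean)
  agg[order(agg$genotype, agg$environment), , drop = FALSE]
}

#' Least-squares genotype means across environments
#'
#' Fits the additive fixed-effects model `value ~ genotype + environment` by
#' least squares with sum-to-zero environment contrasts and returns each
#' genotype's prediction at the average environment. In a balanced design
#' this collapses to the raw genotype means; in unbalanced designs it adjusts
#' for which environments each genotype was observed in. Replicates, if
#' present, are averaged first.
#'
#' The two-way model is only estimable when the genotype x environment
#' incidence graph is connected; a disconnected design is reported with its
#' blocks rather than silently fitted.
#'
#' @param records Phenotype records (long format).
#' @return Data frame with columns `genotype` and `lsmean`.
#' @export
ls_means <- function(records) {
  first_order <- unique(check_records(records)$genotype)
  records <- replicate_means(records)
  gens <- first_order
  envs <- unique(records$environment)
  if (length(envs) == 1) {
    res <- stats::aggregate(value ~ genotype, data = records, FUN = mean)
    return(data.frame(genotype = gens,
                      lsmean = res$value[match(gens, res$genotype)],
                      stringsAsFactors = FALSE))
  }
  comp <- incidence_components(records)
  if (max(comp$block) > 1) {
    blocks <- split(comp$genotype, comp$block)
    stop("genotype x environment design is disconnected; blocks: ",
         paste(vapply(blocks, function(b)
           paste0("{", paste(utils::head(b, 5), collapse = ","),
                  if (length(b) > 5) ",..." else "", "}"), character(1)),
           collapse = " "))
  }
  df <- records
  df$genotype <- factor(df$genotype, levels = gens)
  df$environment <- factor(df$environment, levels = envs)
  fit <- stats::lm(value ~ genotype + environment, data = df,
                   contrasts = list(environment = "contr.sum"))
  grid <- expand.grid(genotype = factor(gens, levels = gens),
                      environment = factor(envs, levels = envs))
  pred <- stats::predict(fit, newdata = grid)
  ls <- tapply(pred, grid$genotype, mean)
  data.frame(genotype = gens, lsmean = as.numeric(ls[gens]),
             stringsAsFactors = FALSE)
}

## connected components of the genotype/environment bipartite graph
incidence_components <- function(records) {
  gens <- unique(records$genotype)
  envs <- unique(records$environment)
  gi <- match(records$genotype, gens)
  ei <- match(records$environment, envs)
  block_g <- rep(0L, length(gens))
  block_e <- rep(0L, length(envs))
  b <- 0L
  for (s in seq_along(gens)) {
    if (block_g[s] > 0L) next
    b <- b + 1L
    queue_g <- s
    while (length(queue_g)) {
      g <- queue_g[1]; queue_g <- queue_g[-1]
      if (block_g[g] > 0L) next
      block_g[g] <- b
      es <- unique(ei[gi == g])
      new_e <- es[block_e[es] == 0L]
      block_e[new_e] <- b
      for (e in new_e)
        queue_g <- c(queue_g, unique(gi[ei == e & block_g[gi] == 0L]))
    }
  }
  data.frame(genotype = gens, block = block_g, stringsAsFactors = FALSE)
}

#' Pearson correlations of genotype means between locations
#'
#' For every pair of environments, computes the Pearson correlation of
#' genotype means over the genotypes observed in both (pairwise complete).
#' Pairs sharing fewer than three genotypes are flagged undefined (`NA`).
#'
#' @param records Phenotype records (long format).
#' @return Data frame with columns `env1`, `env2`, `n_shared`, `r`.
#' @export
location_correlations <- function(records) {
  records <- replicate_means(records)
  envs <- sort(unique(records$environment))
  if (length(envs) < 2) stop("need at least two environments")
  wide <- stats::reshape(records, idvar = "genotype",
                         timevar = "environment", direction = "wide")
  out <- list()
  for (i in seq_len(length(envs) - 1)) {
    for (j in (i + 1):length(envs)) {
      x <- wide[[paste0("value.", envs[i])]]
      y <- wide[[paste0("value.", envs[j])]]
      ok <- !is.na(x) & !is.na(y)
      r <- if (sum(ok) >= 3) stats::cor(x[ok], y[ok]) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        env1 = envs[i], env2 = envs[j], n_shared = sum(ok), r = r,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Trait summary with biofortification-threshold count
#'
#' Mean, range, sample SD, and the count/percentage of genotypes whose
#' adjusted mean reaches a target concentration (default 33.0 mg/kg, the
#' HarvestPlus kernel-Zn breeding target; "reaching" is inclusive).
#'
#' @param means Data frame with columns `genotype` and `lsmean`
#'   (from [ls_means()]).
#' @param threshold Target trait level, same units as the means.
#' @return One-row data frame: `n`, `mean`, `min`, `max`, `sd`,
#'   `n_above`, `pct_above`, `threshold`.
#' @export
summarize_trait <- function(means, threshold = 33.0) {
  if (nrow(means) == 0) stop("no genotype means to summarize")
  v <- means$lsmean
  n_above <- sum(v >= threshold)
  data.frame(n = length(v), mean = mean(v), min = min(v), max = max(v),
             sd = stats::sd(v), n_above = n_above,
             pct_above = 100 * n_above / length(v), threshold = threshold)
}
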