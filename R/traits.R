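# Trait preprocessing: unit conversion, species means, repeatability.
#
# The measurement table holds one row per literature source per species, with
# body mass in grams and brain size either as mass (g) or volume (ml).

# coefficients of the published brain mass -> brain volume regression,
# log10(volume ml) = a + b * log10(mass g)
BRAIN_CONV_INTERCEPT <- -0.102
BRAIN_CONV_SLOPE <- 1.053

#' Convert brain mass to brain volume
#'
#' Applies the allometric conversion
#' `log10(volume) = -0.102 + 1.053 * log10(mass)` fitted on species with both
#' measures, used to fill in volume where only brain mass was reported.
#'
#' @param brain_mass Brain mass in grams (positive).
#' @return Brain volume in ml.
#' @examples
#' brain_mass_to_volume(10)  # 10^0.951
#' @export
brain_mass_to_volume <- function(brain_mass) {
  if (any(!is.finite(brain_mass)) || any(brain_mass <= 0))
    stop("validation error: brain mass must be positive and finite")
  10^(BRAIN_CONV_INTERCEPT + BRAIN_CONV_SLOPE * log10(brain_mass))
}

#' Read a per-source trait measurement table
#'
#' Expected CSV header: `species, source, body_mass_g, brain_mass_g,
#' brain_volume_ml` (the two brain columns may contain NA, but not both in
#' the same row). Units other than g/ml are not supported and any
#' `_kg`/`_cc` style header variant is rejected.
#'
#' @param path CSV file path.
#' @return A `data.frame` of trait records with normalised species labels.
#' @export
read_trait_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "source", "body_mass_g")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trait CSV is missing column(s): ", paste(missing, collapse = ", "))
  if (!any(c("brain_mass_g", "brain_volume_ml") %in% names(df)))
    stop("trait CSV needs at least one of brain_mass_g, brain_volume_ml")
  bad <- grep("_kg$|_cc$|_cm3$|_lb$", names(df), value = TRUE)
  if (length(bad))
    stop("unsupported unit column(s): ", paste(bad, collapse = ", "),
         " (expected body_mass_g, brain_mass_g, brain_volume_ml)")
  if (!"brain_mass_g" %in% names(df)) df$brain_mass_g <- NA_real_
  if (!"brain_volume_ml" %in% names(df)) df$brain_volume_ml <- NA_real_
  df$species <- normalize_labels(df$species)
  validate_trait_records(df)
  df
}

validate_trait_records <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) >= 1)
  for (col in c("body_mass_g", "brain_mass_g", "brain_volume_ml"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  pos_or_na <- function(x) all(is.na(x) | x > 0)
  if (!pos_or_na(df$body_mass_g) || !pos_or_na(df$brain_mass_g) ||
      !pos_or_na(df$brain_volume_ml))
    stop("validation error: trait values must be positive where present")
  if (any(is.na(df$body_mass_g)))
    stop("validation error: body_mass_g missing in some records")
  invisible(df)
}

#' Aggregate per-source measurements into species means
#'
#' For each record the working brain volume is the observed volume when
#' present, otherwise the converted brain mass (see
#' [brain_mass_to_volume()]). Species means are then taken on the raw scale
#' (g, ml) and log10-transformed -- matching how multi-source literature
#' compilations are usually averaged -- or, with `aggregation_scale =
#' "log"`, the log10 values are averaged directly.
#'
#' Species with no usable brain value are excluded from the table but listed
#' in the `rejected` attribute (a data.frame with reason codes), never
#' silently dropped.
#'
#' @param records Trait record data.frame (see [read_trait_csv()]).
#' @param aggregation_scale `"raw"` (default) or `"log"`.
#' @return A `species_traits` data.frame with columns `species`,
#'   `log_body_mass`, `log_brain_volume`, `n_sources`.
#' @export
aggregate_species <- function(records, aggregation_scale = c("raw", "log")) {
  aggregation_scale <- match.arg(aggregation_scale)
  records <- validate_trait_records(records)
  has_brain <- !is.na(records$brain_volume_ml) | !is.na(records$brain_mass_g)
  rejected <- data.frame(species = character(0), reason = character(0))
  no_brain_sp <- setdiff(unique(records$species),
                         unique(records$species[has_brain]))
  if (length(no_brain_sp))
    rejected <- data.frame(species = no_brain_sp, reason = "no_brain_data")
  records <- records[records$species %in% setdiff(unique(records$species),
                                                  no_brain_sp), , drop = FALSE]
  if (nrow(records) == 0)
    stop("validation error: no species with usable brain data")

  vol <- records$brain_volume_ml
  need_conv <- is.na(vol) & !is.na(records$brain_mass_g)
  if (any(need_conv))
    vol[need_conv] <- brain_mass_to_volume(records$brain_mass_g[need_conv])
  sp <- records$species
  mean_by <- function(x) {
    keep <- !is.na(x)
    tapply(x[keep], sp[keep], mean)
  }
  if (aggregation_scale == "raw") {
    lb <- log10(mean_by(records$body_mass_g))
    lv <- log10(mean_by(vol))
  } else {
    lb <- mean_by(log10(records$body_mass_g))
    lv <- mean_by(log10(vol))
  }
  species <- sort(unique(sp))
  out <- data.frame(
    species = species,
    log_body_mass = as.numeric(lb[species]),
    log_brain_volume = as.numeric(lv[species]),
    n_sources = as.integer(table(sp)[species]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("species_traits", "data.frame")
  attr(out, "rejected") <- rejected
  attr(out, "aggregation_scale") <- aggregation_scale
  out
}

#' Within-species repeatability (intraclass correlation)
#'
#' One-way ANOVA variance-components estimate of the intraclass correlation
#' `R = s2_A / (s2_A + s2_W)` across species, where `s2_A = (MS_among -
#' MS_within) / n0` and `n0` is the Lessells-Boag correction for unbalanced
#' group sizes. A high `R` means literature sources agree within species
#' relative to differences among species. The estimate is invariant to
#' species relabeling and to any affine transform of the values; by default
#' values are analysed on the scale supplied, with `log_scale = TRUE`
#' available for traits spanning orders of magnitude. The confidence
#' interval comes from a parametric bootstrap that resamples species effects
#' and within-species errors from the fitted normal components at the
#' observed group sizes.
#'
#' @param records Trait record data.frame.
#' @param trait One of `"body_mass"`, `"brain_mass"`, `"brain_volume"`.
#' @param n_boot Number of bootstrap resamples for the CI.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param log_scale Analyse log10-transformed values.
#' @return A `repeatability_result` list with fields `trait`, `R`, `ci_low`,
#'   `ci_high`, `n_species`, `n_measurements`.
#' @export
repeatability <- function(records, trait = c("body_mass", "brain_mass",
                                             "brain_volume"),
                          n_boot = 1000, seed = 1, conf = 0.95,
                          log_scale = FALSE) {
  trait <- match.arg(trait)
  records <- validate_trait_records(records)
  col <- c(body_mass = "body_mass_g", brain_mass = "brain_mass_g",
           brain_volume = "brain_volume_ml")[[trait]]
  keep <- !is.na(records[[col]])
  values <- records[[col]][keep]
  if (log_scale) values <- log10(values)
  groups <- records$species[keep]
  counts <- table(groups)
  multi <- names(counts)[counts >= 2]
  if (length(multi) < 2)
    stop("validation error: repeatability needs >= 2 species with >= 2 ",
         "measurements each (found ", length(multi), ")")
  sel <- groups %in% multi
  est <- icc_anova(values[sel], groups[sel])

  set.seed(seed)
  ni <- as.integer(table(factor(groups[sel])))
  boots <- replicate(n_boot, {
    mu <- rnorm(length(ni), 0, sqrt(est$s2_among))
    y <- unlist(lapply(seq_along(ni),
                       function(i) rnorm(ni[i], mu[i], sqrt(est$s2_within))))
    g <- rep(seq_along(ni), ni)
    icc_anova(y, g)$R
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  out <- list(trait = trait, R = est$R,
              ci_low = min(ci[1], est$R), ci_high = max(ci[2], est$R),
              n_species = length(multi), n_measurements = sum(sel),
              s2_among = est$s2_among, s2_within = est$s2_within,
              n_boot = n_boot, seed = seed)
  class(out) <- "repeatability_result"
  out
}

# one-way ANOVA ICC with the Lessells-Boag n0 for unbalanced designs
icc_anova <- function(values, groups) {
  g <- factor(groups)
  a <- nlevels(g)
  N <- length(values)
  ni <- as.integer(table(g))
  gm <- tapply(values, g, mean)
  grand <- mean(values)
  ss_among <- sum(ni * (gm - grand)^2)
  ss_within <- sum((values - gm[g])^2)
  ms_among <- ss_among / (a - 1)
  ms_within <- ss_within / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  s2_among <- max((ms_among - ms_within) / n0, 0)
  R <- if (s2_among + ms_within <= 0) 0 else s2_among / (s2_among + ms_within)
  list(R = min(max(R, 0), 1), s2_among = s2_among, s2_within = ms_within,
       ms_among = ms_among, ms_within = ms_within, n0 = n0)
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability of %s: R = %.3f, %s CI = [%.3f, %.3f]\n",
              x$trait, x$R, "95%", x$ci_low, x$ci_high))
  cat(sprintf("  %d species, %d measurements (%d bootstrap reps)\n",
              x$n_species, x$n_measurements, x$n_boot))
  invisible(x)
}

#' Write a species trait table to CSV
#' @param table A `species_traits` data.frame.
#' @param path Output path.
#' @export
write_species_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  rej <- attr(table, "rejected")
  if (!is.null(rej) && nrow(rej) > 0)
    write.csv(rej, sub("\\.csv$", "_rejected.csv", path), row.names = FALSE)
  invisible(path)
}
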