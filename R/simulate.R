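# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure the analysis assumes: every tissue
# sample's allelic score is the founder fraction k/N of an independent
# binomial draw (clonal mosaicism), X-inactivation scores are the same model
# at p = 0.5 in females, and qPCR Ct tables carry group fold-change effects
# on the delta-Ct scale.

#' Simulate allelic scores under the founder-sampling model
#'
#' Draws `n_samples` scores `k / n_founders` with
#' `k ~ Binomial(n_founders, p)`, optionally adding Gaussian densitometry
#' noise truncated to \[0, 1\]. Output is fully determined by `seed`.
#'
#' @param n_founders True founder cell number (positive integer).
#' @param p Per-cell "on" probability in (0, 1).
#' @param n_samples Number of scores to draw.
#' @param noise_sd Gaussian measurement noise SD (default 0).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can manage seeding themselves).
#' @return Numeric vector of scores. When noise truncation occurred, the
#'   number of truncated values is attached as attribute `n_truncated` and
#'   reported via a message.
#' @export
simulate_founder_scores <- function(n_founders, p, n_samples, noise_sd = 0,
                                    seed = NULL) {
  stopifnot(n_founders >= 1, n_founders == as.integer(n_founders),
            p > 0, p < 1, n_samples >= 1, noise_sd >= 0)
  draw <- function() {
    s <- rbinom(n_samples, n_founders, p) / n_founders
    if (noise_sd > 0) {
      s <- s + rnorm(n_samples, 0, noise_sd)
      n_trunc <- sum(s < 0 | s > 1)
      s <- pmin(pmax(s, 0), 1)
      if (n_trunc > 0) {
        inform(sprintf("%d noisy score(s) truncated to [0, 1]", n_trunc))
        attr(s, "n_truncated") <- n_trunc
      }
    }
    s
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Default group fold-change effects for the Ct simulator
#'
#' Transcript-level fold changes (in vitro relative to in vivo) injected by
#' [simulate_cohort()], one per gene and tissue class. The defaults are the
#' effect sizes reported for an ART cohort: reduced placental IGF2 (0.52)
#' and H19 (0.72), reduced cord-blood IGF2R (0.61), and near-null effects
#' elsewhere.
#'
#' @return A tibble with columns `gene`, `tissue_class`, `fold`.
#' @export
default_fold_effects <- function() {
  tibble(
    gene = c("H19", "IGF2", "IGF2R", "H19", "IGF2", "IGF2R"),
    tissue_class = c(rep("cord_blood", 3), rep("placenta", 3)),
    fold = c(0.88, 1.03, 0.61, 0.72, 0.52, 1.18)
  )
}

#' Configuration of a synthetic cohort
#'
#' Bundles every parameter of the generator. Defaults mirror the study
#' design the package targets: 45 in vitro and 56 in vivo informative
#' newborns, seven tissue samples each (cord blood, cord, five placenta
#' sections), maternal IGF2/H19 DMR methylation probability 0.1, balanced
#' X-inactivation probability 0.5, founder counts 8 (in vitro) vs 10
#' (in vivo), and a larger expression cohort (98 vs 160) carrying the
#' fold-change effects of [default_fold_effects()].
#'
#' @param n_in_vitro,n_in_vivo Individuals per conception group in the
#'   methylation cohort.
#' @param founders_in_vitro,founders_in_vivo True founder cell numbers.
#' @param p_dmr Maternal-methylation probability at the IGF2/H19 DMR.
#' @param p_xi X-inactivation probability (0.5; fixed by X-chromosome
#'   biology, exposed only for sensitivity analysis).
#' @param p_igf2r Optional paternal-methylation probability at the IGF2R
#'   DMR; `NULL` (default) disables the PM assay.
#' @param tissues Ordered tissue sample labels.
#' @param noise_sd Densitometry noise SD added to scores (default 0).
#' @param fold_effects Tibble `gene` x `tissue_class` -> `fold` (in vitro
#'   relative to in vivo); see [default_fold_effects()].
#' @param ct_sd Technical SD of each Ct measurement, in cycles
#'   (default 0.1, a typical qPCR replicate SD).
#' @param ct_baselines Named per-gene baseline Ct values; only differences
#'   matter to the delta-delta-Ct method.
#' @param n_expr_in_vitro,n_expr_in_vivo Individuals per group in the
#'   expression (qPCR) cohort.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_in_vitro = 45, n_in_vivo = 56,
                          founders_in_vitro = 8, founders_in_vivo = 10,
                          p_dmr = 0.1, p_xi = 0.5, p_igf2r = NULL,
                          tissues = ef_tissues(), noise_sd = 0,
                          fold_effects = default_fold_effects(),
                          ct_sd = 0.1,
                          ct_baselines = c(IGF2 = 25, H19 = 25,
                                           IGF2R = 25, GAPDH = 20),
                          n_expr_in_vitro = 98, n_expr_in_vivo = 160,
                          seed = 1L) {
  stopifnot(
    n_in_vitro >= 1, n_in_vivo >= 1,
    founders_in_vitro >= 1, founders_in_vivo >= 1,
    p_dmr > 0, p_dmr < 1, p_xi > 0, p_xi < 1,
    is.null(p_igf2r) || (p_igf2r > 0 && p_igf2r < 1),
    noise_sd >= 0, ct_sd >= 0,
    n_expr_in_vitro >= 2, n_expr_in_vivo >= 2,
    length(seed) == 1, is.finite(seed)
  )
  if (!all(tissues %in% ef_tissues())) {
    abort(paste0("unknown tissue label(s); allowed: ",
                 paste(ef_tissues(), collapse = ", ")))
  }
  stopifnot(all(c("gene", "tissue_class", "fold") %in% names(fold_effects)))
  structure(
    list(
      n_in_vitro = as.integer(n_in_vitro), n_in_vivo = as.integer(n_in_vivo),
      founders_in_vitro = as.integer(founders_in_vitro),
      founders_in_vivo = as.integer(founders_in_vivo),
      p_dmr = p_dmr, p_xi = p_xi, p_igf2r = p_igf2r,
      tissues = tissues, noise_sd = noise_sd,
      fold_effects = as_tibble(fold_effects), ct_sd = ct_sd,
      ct_baselines = ct_baselines,
      n_expr_in_vitro = as.integer(n_expr_in_vitro),
      n_expr_in_vivo = as.integer(n_expr_in_vivo),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Read a cohort configuration from YAML
#'
#' The YAML keys mirror the arguments of [cohort_config()];
#' `fold_effects`, if present, is a list of `{gene, tissue_class, fold}`
#' mappings.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$fold_effects)) {
    raw$fold_effects <- dplyr::bind_rows(lapply(raw$fold_effects, as_tibble))
  }
  do.call(cohort_config, raw)
}

#' Simulate a full cohort
#'
#' Generates the two tables consumed downstream:
#'
#' * a **ratio table**: per individual and tissue sample, an `MP` score at
#'   `IGF2_H19` (all individuals), an `XI` score at `AR` (females only, sex
#'   assigned Bernoulli(0.5)), and optionally a `PM` score at `IGF2R`; each
#'   score is an independent draw from [simulate_founder_scores()] with the
#'   group's founder count;
#' * a **Ct table** for a separate expression cohort: per individual,
#'   cord-blood and placental Ct values for IGF2, H19, IGF2R and the GAPDH
#'   housekeeping gene, with the in vitro group's target delta-Ct shifted by
#'   `-log2(fold)` per `fold_effects`.
#'
#' The configuration seed fully determines both tables.
#'
#' @param config A [cohort_config()].
#' @return A list with tibbles `ratios` and `ct`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config() or read_cohort_config()")
  }
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  tissues <- config$tissues
  n_tis <- length(tissues)

  group_frame <- function(group, n_ind, founders) {
    ids <- sprintf("%s_%03d", ifelse(group == "in_vitro", "vtr", "vvo"),
                   seq_len(n_ind))
    female <- rbinom(n_ind, 1, 0.5) == 1
    base <- tidyr::expand_grid(individual_id = ids, tissue = tissues) |>
      dplyr::mutate(group = group)

    mp <- base |>
      dplyr::mutate(
        locus = "IGF2_H19", score_kind = "MP",
        value = simulate_founder_scores(founders, config$p_dmr,
                                        n_ind * n_tis, config$noise_sd)
      )
    xi <- base |>
      dplyr::filter(.data$individual_id %in% ids[female])
    if (nrow(xi) > 0) {
      xi <- xi |>
        dplyr::mutate(
          locus = "AR", score_kind = "XI",
          value = simulate_founder_scores(founders, config$p_xi,
                                          nrow(xi), config$noise_sd)
        )
    }
    out <- dplyr::bind_rows(mp, xi)
    if (!is.null(config$p_igf2r)) {
      pm <- base |>
        dplyr::mutate(
          locus = "IGF2R", score_kind = "PM",
          value = simulate_founder_scores(founders, config$p_igf2r,
                                          n_ind * n_tis, config$noise_sd)
        )
      out <- dplyr::bind_rows(out, pm)
    }
    out
  }

  ratios <- dplyr::bind_rows(
    group_frame("in_vitro", config$n_in_vitro, config$founders_in_vitro),
    group_frame("in_vivo", config$n_in_vivo, config$founders_in_vivo)
  ) |>
    dplyr::select("individual_id", "group", "tissue", "locus",
                  "score_kind", "value")

  ct <- simulate_ct_table(config)
  list(ratios = ratios, ct = ct)
}

simulate_ct_table <- function(config) {
  genes <- names(config$ct_baselines)
  housekeeping <- "GAPDH"
  expr_tissues <- c("cord_blood", "placenta_1")

  expr_group <- function(group, n_ind) {
    ids <- sprintf("%s_e%03d", ifelse(group == "in_vitro", "vtr", "vvo"),
                   seq_len(n_ind))
    tidyr::expand_grid(individual_id = ids, tissue = expr_tissues,
                       gene = genes) |>
      dplyr::mutate(group = group)
  }

  fold_by_tissue <- dplyr::bind_rows(
    lapply(expr_tissues, function(t) {
      config$fold_effects |>
        dplyr::filter(.data$tissue_class == ef_tissue_class(t)) |>
        dplyr::mutate(tissue = t)
    })
  ) |>
    dplyr::select("gene", "tissue", "fold")

  ct <- dplyr::bind_rows(
    expr_group("in_vitro", config$n_expr_in_vitro),
    expr_group("in_vivo", config$n_expr_in_vivo)
  ) |>
    dplyr::left_join(fold_by_tissue, by = c("gene", "tissue")) |>
    dplyr::mutate(
      fold = dplyr::coalesce(.data$fold, 1),
      shift = dplyr::if_else(
        .data$group == "in_vitro" & .data$gene != housekeeping,
        -log2(.data$fold), 0
      ),
      ct = unname(config$ct_baselines[.data$gene]) + .data$shift +
        rnorm(dplyr::n(), 0, config$ct_sd)
    ) |>
    dplyr::select("individual_id", "group", "tissue", "gene", "ct")
  ct
}
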