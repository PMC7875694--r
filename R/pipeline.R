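#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage in order: generate the study bundle (traits,
#' raw streams), clean the streams, extract trait-level and daily features,
#' run the trait pipeline (correlations, Lasso-selected OLS, LOSO-SVR) and
#' the daily state pipeline (GEE + median-split LOSO classification), and
#' optionally write JSON reports with a reproducibility manifest.
#'
#' @param config A [cohort_config]; its seed determines every random draw.
#' @param out_dir Optional directory for `trait_report.json`,
#'   `state_report.json`, and `manifest.json`.
#' @return List with `bundle`, `trait_report`, `state_report`,
#'   `correlations`, and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL) {
  bundle <- generate_bundle(config)
  cors <- correlate_traits(
    bundle$trait_features[feature_names()],
    bundle$traits[intersect(TRAIT_OUTCOMES, names(bundle$traits))]
  )
  trait_rep <- run_trait_battery(bundle$trait_features, bundle$traits)
  feat_rows <- bundle$daily_features[
    match(interaction(bundle$daily$participant_id, bundle$daily$morning_time),
          interaction(bundle$daily_features$participant_id,
                      bundle$daily_features$morning_time)), , drop = FALSE]
  state_rep <- run_state_battery(feat_rows, bundle$daily)
  manifest <- list(
    seed = config$seed,
    n_participants = config$n_participants,
    n_days = config$n_days,
    filter_fractions = bundle$filter_fractions,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("impulsense"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(trait_report_json(trait_rep),
                         file.path(out_dir, "trait_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(state_report_json(state_rep),
                         file.path(out_dir, "state_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(bundle = bundle, correlations = cors, trait_report = trait_rep,
       state_report = state_rep, manifest = manifest)
}

# JSON-friendly view of the trait battery, mirroring the usual reporting
# columns (selected features, F on (df1, df2), adjusted R^2, LOSO MAE and r).
trait_report_json <- function(rep) {
  lapply(rep, function(x) {
    list(
      outcome = x$outcome,
      selected = x$selected,
      model = if (is.null(x$model)) NULL else list(
        F = x$model$F, df1 = x$model$df1, df2 = x$model$df2, p = x$model$p,
        r2 = x$model$r2, adj_r2 = x$model$adj_r2,
        coefficients = x$model$coefficients
      ),
      loso = if (is.null(x$loso)) NULL else list(
        mae = x$loso$mae, r = x$loso$r, p = x$loso$p
      )
    )
  })
}

state_report_json <- function(rep) {
  lapply(rep, function(x) {
    list(
      outcome = x$outcome, r = x$r, p = x$p,
      within_group_correlation = x$within_group_correlation,
      mean_accuracy = x$classification$mean_accuracy,
      sd_accuracy = x$classification$sd_accuracy
    )
  })
}
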