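## CPU-time benchmarking harness: the eight implementation-choice
## timing experiments, the repetition protocol, and Welch comparisons.

#' Time repeated executions of a batch closure
#'
#' Runs the closure `n_reps` times, measuring the per-repetition CPU
#' (process) time -- not wall-clock time -- of the whole batch, and
#' collecting the solve-only CPU sub-span that [run_batch()] attaches to
#' its result.  One-time setup belongs outside the closure; the closure
#' itself should contain only per-subject work.
#'
#' @param batch_fn zero-argument closure executing one batch (typically
#'   wrapping [run_batch()]); its return value's `solve_cpu` attribute,
#'   if present, is recorded as the solve-only span.
#' @param n_reps number of repetitions (>= 2).
#' @param experiment,variant,batch_size,scenario,chemical metadata
#'   stored on the record.
#' @return object of class `timing_record` with per-rep `batch_cpu` and
#'   `solve_cpu` vectors (seconds).
#' @export
time_batch <- function(batch_fn, n_reps = 10, experiment = NA,
                       variant = "variant", batch_size = NA,
                       scenario = NA, chemical = NA) {
  stopifnot(is.function(batch_fn), n_reps >= 2)
  batch_cpu <- numeric(n_reps)
  solve_cpu <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    t0 <- proc.time()
    res <- batch_fn()
    dt <- proc.time() - t0
    batch_cpu[r] <- sum(dt[c("user.self", "sys.self")])
    sc <- attr(res, "solve_cpu")
    solve_cpu[r] <- if (is.null(sc)) NA_real_ else sc
  }
  if (all(batch_cpu < 1e-3))
    warning("batch CPU times are below timer resolution (~1 ms)")
  structure(list(experiment = experiment, variant = variant,
                 n_reps = n_reps, batch_cpu = batch_cpu,
                 solve_cpu = solve_cpu, batch_size = batch_size,
                 scenario = scenario, chemical = chemical),
            class = "timing_record")
}

#' Compare two timing records
#'
#' Welch's unequal-variance two-sample t-test on the per-repetition
#' batch CPU times; a difference is flagged significant at p < 0.05.
#'
#' @param a,b `timing_record` objects for the same experiment, batch
#'   size and scenario.
#' @return object of class `timing_comparison`: variant labels, mean
#'   difference (a - b, seconds), p-value and significance flag.
#' @export
compare_timings <- function(a, b) {
  stopifnot(inherits(a, "timing_record"), inherits(b, "timing_record"))
  same <- function(x, y) (is.na(x) && is.na(y)) || isTRUE(x == y)
  if (!same(a$experiment, b$experiment) ||
      !same(a$batch_size, b$batch_size) || !same(a$scenario, b$scenario))
    stop("timing records come from different experimental conditions",
         call. = FALSE)
  if (stats::sd(a$batch_cpu) == 0 && stats::sd(b$batch_cpu) == 0 &&
      mean(a$batch_cpu) == mean(b$batch_cpu)) {
    p <- 1
  } else {
    p <- tryCatch(
      stats::t.test(a$batch_cpu, b$batch_cpu, var.equal = FALSE)$p.value,
      error = function(e) 1)
  }
  structure(list(variant_a = a$variant, variant_b = b$variant,
                 mean_diff = mean(a$batch_cpu) - mean(b$batch_cpu),
                 p_value = p, significant = p < 0.05),
            class = "timing_comparison")
}

## Variant definitions for the eight experiments.  Each variant is a
## list(label, config modifier or engine factory kind, n_points).
.experiment_variants <- function(id, chemical) {
  base <- function(...) template_config(chemical, ...)
  tmpl <- function(cfg) list(kind = "template", config = cfg)
  sa <- list(kind = "standalone")
  v <- switch(as.character(id),
    "1" = list(template = tmpl(base()), standalone = sa),
    "2" = list(ternary = tmpl(base(conditional_mode = "BRANCH")),
               switches = tmpl(base(conditional_mode = "SWITCH"))),
    "3" = list(points_50 = c(tmpl(base()), n_points = 50),
               points_100 = c(tmpl(base()), n_points = 100),
               points_500 = c(tmpl(base()), n_points = 500)),
    "4" = list(outputs_105 = tmpl(base(reduced_outputs = FALSE)),
               outputs_76 = tmpl(base(reduced_outputs = TRUE))),
    "5" = list(bw_input = tmpl(base(bw_mode = "INPUT_TABLE")),
               bw_fixed_dynamic = tmpl(base(bw_mode = "FIXED_DYNAMIC")),
               bw_fixed_init = tmpl(base(bw_mode = "FIXED_INIT"))),
    "6" = list(full = tmpl(base(prune = FALSE)),
               pruned = tmpl(base(prune = TRUE))),
    "7" = list(blood_ss = tmpl(base(blood_mode = "SS_APPROX")),
               blood_states = tmpl(base(blood_mode = "STATE_VARS"))),
    "8" = .lung_ge_variants(chemical),
    stop("unknown experiment id: ", id, call. = FALSE))
  v
}

.lung_ge_variants <- function(chemical) {
  cfg0 <- template_config(chemical)
  with_lung <- union(cfg0$active_compartments, "lung_tissue")
  no_lung <- setdiff(cfg0$active_compartments, "lung_tissue")
  no_lung_paths <- setdiff(cfg0$active_pathways, c("sat_lung", "fo_lung"))
  mk <- function(comp, paths, lung, ge)
    list(kind = "template",
         config = template_config(chemical, active_compartments = comp,
                                  active_pathways = paths,
                                  lung_present = lung,
                                  gas_exchange_mode = ge))
  list(no_lung_ge_ss = mk(no_lung, no_lung_paths, FALSE, "GE_SS"),
       lung_ge_ss = mk(with_lung, cfg0$active_pathways, TRUE, "GE_SS"),
       lung_ge_state = mk(with_lung, cfg0$active_pathways, TRUE,
                          "GE_STATE"))
}

#' Run one of the eight timing experiments
#'
#' Builds the variant implementations the experiment compares --
#' (1) template vs stand-alone; (2) ternary conditionals vs
#' multiplicative switches; (3) 50/100/500 requested output points;
#' (4) 105 vs 76 output variables; (5) the three body-weight handling
#' modes; (6) full vs pruned state roster; (7) blood steady-state
#' approximation vs blood state variables; (8) the lung / gas-exchange
#' representation triple -- times each over a seeded virtual-subject
#' batch with the repetition protocol, and tabulates means and standard
#' deviations plus pairwise Welch comparisons against the first variant.
#'
#' @param id experiment number, 1-8.
#' @param chemicals chemicals to run (`"dcm"`, `"cf"`).
#' @param scenarios exposure scenario kinds (subset of 1:4).
#' @param batch_size virtual subjects per batch.
#' @param n_reps timing repetitions per variant.
#' @param seed population seed.
#' @param n_points default output grid (overridden by experiment 3).
#' @param dose_level exposure level passed to [make_scenario()].
#' @return data.frame with columns `experiment`, `chemical`, `scenario`,
#'   `variant`, `mean_s`, `sd_s`, `n`; attributes `records` (the
#'   `timing_record`s) and `comparisons`.
#' @export
run_experiment <- function(id, chemicals = "dcm", scenarios = 1,
                           batch_size = 100, n_reps = 10, seed = 1,
                           n_points = 100, dose_level = 0.35) {
  stopifnot(id %in% 1:8)
  rows <- list(); records <- list(); comparisons <- list()
  for (chemical in chemicals) {
    chem <- chemical_fixture(chemical)
    pop <- sample_population(population_spec(batch_size, seed = seed))
    for (scen in scenarios) {
      dl <- if (scen %in% c(2, 4)) 50 else dose_level
      schedule <- make_scenario(scen, dl)
      variants <- .experiment_variants(id, chemical)
      recs <- list()
      for (vn in names(variants)) {
        v <- variants[[vn]]
        np <- if (!is.null(v$n_points)) v$n_points else n_points
        factory <- if (v$kind == "standalone") {
          function(subj) build_standalone(chemical, chem, subj)
        } else {
          cfg <- v$config
          if (cfg$bw_mode == "INPUT_TABLE") {
            function(subj) build_engine(cfg, chem, subj,
              bw_input = data.frame(time = c(0, 336),
                                    bw = rep(subj[["body_weight"]], 2)))
          } else {
            function(subj) build_engine(cfg, chem, subj)
          }
        }
        rec <- time_batch(
          function() run_batch(factory, pop, schedule, n_points = np),
          n_reps = n_reps, experiment = id, variant = vn,
          batch_size = batch_size, scenario = scen, chemical = chemical)
        recs[[vn]] <- rec
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = id, chemical = chemical, scenario = scen,
          variant = vn, mean_s = mean(rec$batch_cpu),
          sd_s = stats::sd(rec$batch_cpu), n = n_reps,
          stringsAsFactors = FALSE)
      }
      records <- c(records, recs)
      if (length(recs) > 1) {
        for (vn in names(recs)[-1]) {
          comparisons[[paste(chemical, scen, names(recs)[1], "vs", vn)]] <-
            compare_timings(recs[[1]], recs[[vn]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "records") <- records
  attr(out, "comparisons") <- comparisons
  out
}

#' @export
print.timing_record <- function(x, ...) {
  cat("<timing_record> exp", x$experiment, "|", x$variant, "| n =",
      x$n_reps, "| batch", x$batch_size, "\n")
  cat("  batch CPU:", signif(mean(x$batch_cpu), 4), "+/-",
      signif(stats::sd(x$batch_cpu), 3), "s\n")
  invisible(x)
}

#' @export
print.timing_comparison <- function(x, ...) {
  cat("<timing_comparison>", x$variant_a, "vs", x$variant_b,
      "| diff", signif(x$mean_diff, 4), "s | p =",
      format.pval(x$p_value, digits = 3),
      if (x$significant) "(significant)" else "", "\n")
  invisible(x)
}
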