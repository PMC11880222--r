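## Seeded Monte-Carlo sampling of virtual-subject physiology records.
##
## The default distributions are a documented stand-in for the (not
## publicly printed) human variability distributions the original
## Monte-Carlo analyses drew from: body weight lognormal (median 70 kg,
## CV 20%), fractional volumes and flows normal (CV 20%), all truncated
## at +/- 3 SD, with flow fractions renormalized to sum to 1.

#' Specify a virtual population
#'
#' @param n number of subjects (>= 1; 0 allowed for vacuous batches).
#' @param seed integer RNG seed; the sample is a pure function of the
#'   spec, and subject i is identical for any n >= i (per-subject
#'   streams), so subsets are stable when n changes.
#' @param reference a `physiology_params` record giving the location of
#'   every distribution.
#' @param cv named numeric vector of coefficients of variation by
#'   parameter name (defaults: 0.2 for body weight, volume and flow
#'   fractions; 0 i.e. fixed for the allometric coefficients unless
#'   overridden).
#' @param family named character vector, `"lognormal"` or `"normal"`
#'   per parameter (default: lognormal for body weight, normal for
#'   fractions).
#' @param truncate_sd symmetric truncation bound in SD units (>= 1).
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n, seed = 1L,
                            reference = physiology_fixture(),
                            cv = NULL, family = NULL,
                            truncate_sd = 3) {
  stopifnot(n >= 0, truncate_sd >= 1)
  keys <- physiology_param_names()
  cv_all <- stats::setNames(rep(0, length(keys)), keys)
  varied <- c("body_weight",
              grep("^volume_fraction_|^flow_fraction_", keys, value = TRUE))
  cv_all[varied] <- 0.2
  if (!is.null(cv)) {
    bad <- setdiff(names(cv), keys)
    if (length(bad)) stop("unknown cv keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (any(cv < 0)) stop("CVs must be >= 0", call. = FALSE)
    cv_all[names(cv)] <- cv
  }
  fam_all <- stats::setNames(rep("normal", length(keys)), keys)
  fam_all["body_weight"] <- "lognormal"
  if (!is.null(family)) {
    bad <- setdiff(unique(family), c("normal", "lognormal"))
    if (length(bad)) stop("invalid distribution family: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    fam_all[names(family)] <- family
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 reference = reference, cv = cv_all, family = fam_all,
                 truncate_sd = truncate_sd),
            class = "population_spec")
}

## one truncated draw; rejection sampling (acceptance >= 99.7% at 3 SD)
.draw_trunc <- function(location, cv, family, bound) {
  if (cv == 0) return(location)
  if (family == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(location)          # location is the median
    repeat {
      z <- stats::rnorm(1)
      if (abs(z) <= bound) return(exp(meanlog + sdlog * z))
    }
  } else {
    sd <- location * cv
    repeat {
      z <- stats::rnorm(1)
      if (abs(z) <= bound) return(location + sd * z)
    }
  }
}

#' Sample a virtual population
#'
#' Draws `spec$n` physiology records.  The slowly perfused compartment
#' acts as the balance compartment: all other volume fractions are
#' sampled from their truncated distributions and the slowly perfused
#' fraction is the remainder up to the reference total body fraction,
#' so the sum constraint holds by construction and the sampled marginal
#' means stay unbiased (a subject is redrawn only in the pathological
#' case of a nonpositive remainder).  Flow fractions are renormalized
#' to sum to exactly 1.  Subject i is generated from its own RNG
#' substream seeded by `(seed, i)`, so the first k subjects are
#' identical for any n >= k.
#'
#' @param spec a [population_spec()].
#' @return list of `physiology_params` records.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  ref <- spec$reference
  keys <- physiology_param_names()
  ffk <- paste0("flow_fraction_", .PERFUSED)
  vfk <- paste0("volume_fraction_", .VOLUME_COMPARTMENTS)
  vf_total <- sum(as.numeric(ref[vfk]))
  sampled_keys <- setdiff(keys, "volume_fraction_slowly")
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    ## per-subject stream: stable under changes of n
    set.seed(spec$seed * 1000003L %% 2147483647L + i)
    repeat {
      vals <- stats::setNames(numeric(length(keys)), keys)
      for (k in sampled_keys)
        vals[[k]] <- .draw_trunc(as.numeric(ref[[k]]), spec$cv[[k]],
                                 spec$family[[k]], spec$truncate_sd)
      vals[["volume_fraction_slowly"]] <-
        vf_total - sum(vals[setdiff(vfk, "volume_fraction_slowly")])
      if (vals[["volume_fraction_slowly"]] <= 0) next
      subj <- tryCatch(physiology_params(vals), error = function(e) NULL)
      if (!is.null(subj)) break
    }
    ff <- as.numeric(subj[ffk])
    subj[ffk] <- ff / sum(ff)
    out[[i]] <- structure(unclass(subj), class = "physiology_params")
  }
  class(out) <- c("pbpk_population", "list")
  out
}

#' Take the leading subset of a population
#'
#' Order-preserving: the first `k` records.
#'
#' @param population a [sample_population()] result.
#' @param k number of subjects to keep (0 <= k <= length).
#' @return a `pbpk_population` of length `k`.
#' @export
subset_population <- function(population, k) {
  stopifnot(inherits(population, "pbpk_population"))
  if (k > length(population))
    stop("k = ", k, " exceeds population size ", length(population),
         call. = FALSE)
  out <- population[seq_len(k)]
  class(out) <- c("pbpk_population", "list")
  out
}

#' Write a population as CSV (one row per subject)
#'
#' @param population a `pbpk_population`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  m <- do.call(rbind, lapply(population, unclass))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pbpk_population <- function(x, ...) {
  cat("<pbpk_population>", length(x), "virtual subjects\n")
  if (length(x)) {
    bw <- vapply(x, function(s) s[["body_weight"]], numeric(1))
    cat("  body weight: median", signif(stats::median(bw), 4), "kg, range",
        signif(min(bw), 4), "-", signif(max(bw), 4), "\n")
  }
  invisible(x)
}
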