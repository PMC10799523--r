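# Synthetic sepsis cohort generator.
#
# Emulates the statistical structure of a small ICU sepsis metabolomics
# cohort: ~50 patients, ~60 quantified plasma metabolites (log-normal
# concentrations with exchangeable correlation), two continuous endothelial
# damage markers (PECAM, sTM) driven by sparse linear effects of the
# log-concentrations, a binary 30-day survival outcome with a fixed number of
# deaths, and clinical covariates (SOFA, septic shock, age, sex, BMI). Ground
# truth coefficients are carried along for recovery tests.

default_sparse_beta <- function(p, idx, values) {
  b <- numeric(p)
  keep <- idx <= p          # small matrices keep whatever effects fit
  b[idx[keep]] <- values[keep]
  b
}

# Built-in roster of plasma metabolites commonly quantified on targeted
# UHPLC-MS/GC-MS panels (amino acids, acylcarnitines, TCA intermediates,
# lipid mediators, purines, hexoses, osmolytes, bile acids). Using real
# names lets synthetic model supports map onto pathway collections.
plasma_metabolite_roster <- c(
  "glycine", "isoleucine", "asparagine", "glutamate", "tyrosine",
  "pyruvate", "fumarate", "oxoproline", "butyrylcarnitine",
  "docosahexanoate", "glutamine", "histidine", "myristoylcarnitine",
  "sphingosine_1_phosphate", "urate", "ornithine", "tryptophan", "cystine",
  "acetylcarnitine", "eicosapentanoate", "linoleate", "kynurenine",
  "octanylcarnitine", "trimethyl_n_oxide", "valine", "threonine",
  "phenylalanine", "aspartate", "succinate", "arachidonate", "arginine",
  "gamma_linolenicate_a", "glucose", "linolenate", "propionylcarnitine",
  "carnitine", "citrate", "malate", "oxaloacetate", "lactate",
  "hypoxanthine", "xanthine", "inosine", "fructose", "galactose",
  "mannose", "creatinine", "urea", "choline", "betaine", "taurine",
  "adenosine", "guanosine", "cytidine", "uridine", "thymidine", "cholate",
  "deoxycholate", "glycocholate", "taurocholate", "chenodeoxycholate",
  "lithocholate", "alanine")

#' Specification of a synthetic sepsis cohort
#'
#' Defaults mirror the cohort the pipeline was designed around: 52 patients,
#' 63 quantified metabolites, 19 deaths within 30 days, and 13 metabolites
#' carrying more than 10% missing values. Planted effect vectors are sparse
#' on the log-concentration scale; the defaults overlap across the three
#' responses (mortality, PECAM, sTM) so that cross-model overlap reporting is
#' exercised.
#'
#' @param n_patients number of patients.
#' @param n_metabolites number of quantified metabolites.
#' @param n_deaths number of 30-day deaths (exactly this many are generated).
#' @param true_beta_mortality,true_beta_pecam,true_beta_stm sparse coefficient
#'   vectors of length `n_metabolites` on the log-concentration scale. `NULL`
#'   uses built-in overlapping defaults.
#' @param noise_sd_markers Gaussian noise SD added to the PECAM and sTM linear
#'   predictors (ng/mL scale).
#' @param missing_rate cell-wise missing-completely-at-random rate in `[0, 1)`.
#' @param n_high_missing_features number of metabolites forced above the 10%
#'   missingness threshold.
#' @param rho exchangeable correlation between metabolite log-concentrations.
#' @param mortality_link `"logistic"` (default) or `"linear"` link from the
#'   sparse linear predictor to the death probability.
#' @param missing_mechanism `"mcar"` (default) or `"mar"`; under `"mar"` low
#'   concentrations are more likely to be masked.
#' @param seed integer seed; the same spec and seed give byte-identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 52, n_metabolites = 63, n_deaths = 19,
                        true_beta_mortality = NULL,
                        true_beta_pecam = NULL,
                        true_beta_stm = NULL,
                        noise_sd_markers = 1.5,
                        missing_rate = 0.03,
                        n_high_missing_features = 13,
                        rho = 0.2,
                        mortality_link = c("logistic", "linear"),
                        missing_mechanism = c("mcar", "mar"),
                        seed = 1L) {
  mortality_link <- match.arg(mortality_link)
  missing_mechanism <- match.arg(missing_mechanism)
  p <- n_metabolites
  # defaults plant overlapping sparse effects: two metabolites (roster
  # positions 12 and 15: histidine, urate) positive for all three responses,
  # one (position 14: sphingosine 1-phosphate) negative for all three, plus
  # response-specific effects -- the overlap structure the reporting stage
  # is designed to surface
  if (is.null(true_beta_mortality))
    true_beta_mortality <- default_sparse_beta(
      p, c(2, 5, 12, 14, 15), c(-1, 0.6, 1, -0.8, 0.8))
  if (is.null(true_beta_pecam))
    true_beta_pecam <- default_sparse_beta(
      p, c(1, 12, 14, 15, 26), c(-1.5, 2, -2, 2.5, 2))
  if (is.null(true_beta_stm))
    true_beta_stm <- default_sparse_beta(
      p, c(7, 12, 14, 15), c(1.8, 2, -2, 1))

  spec <- list(n_patients = as.integer(n_patients),
               n_metabolites = as.integer(p),
               n_deaths = as.integer(n_deaths),
               true_beta_mortality = true_beta_mortality,
               true_beta_pecam = true_beta_pecam,
               true_beta_stm = true_beta_stm,
               noise_sd_markers = noise_sd_markers,
               missing_rate = missing_rate,
               n_high_missing_features = as.integer(n_high_missing_features),
               rho = rho,
               mortality_link = mortality_link,
               missing_mechanism = missing_mechanism,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_deaths >= n_patients) abort_fmt("n_deaths must be < n_patients")
    if (n_deaths < 1) abort_fmt("n_deaths must be >= 1")
    if (missing_rate < 0 || missing_rate >= 1)
      abort_fmt("missing_rate must lie in [0, 1)")
    if (length(true_beta_mortality) != n_metabolites ||
        length(true_beta_pecam) != n_metabolites ||
        length(true_beta_stm) != n_metabolites)
      abort_fmt("planted coefficient vectors must have length n_metabolites")
    if (n_high_missing_features > n_metabolites)
      abort_fmt("n_high_missing_features exceeds n_metabolites")
    if (noise_sd_markers <= 0) abort_fmt("noise_sd_markers must be positive")
  })
  invisible(spec)
}

#' Generate a synthetic cohort
#'
#' Log-concentrations are multivariate normal with exchangeable correlation
#' `rho`; concentrations are their exponentials (so all observed values are
#' positive). PECAM and sTM are linear in the centred log-concentrations with
#' Gaussian noise; 30-day survival is Bernoulli with a logistic (default) or
#' clipped-linear probability, with the intercept calibrated so the expected
#' number of deaths equals `n_deaths`, and draws are rejected until exactly
#' `n_deaths` deaths occur. Missingness is planted separately by
#' [plant_missingness()] according to `spec$missing_rate`.
#'
#' @param spec a [cohort_spec()].
#' @param max_tries maximum rejection draws for the exact event count.
#' @return an object of class `cohort`: a list with `metabolites` (patients x
#'   metabolites concentration matrix, `NA` = missing), `clinical` (data frame
#'   with `survival30`, `pecam`, `stm`, `sofa`, `septic_shock`, `age`, `sex`,
#'   `bmi`) and `truth` (the generating spec).
#' @export
make_cohort <- function(spec, max_tries = 10000L) {
  validate_cohort_spec(spec)
  n <- spec$n_patients; p <- spec$n_metabolites
  with_seed(spec$seed, {
    # exchangeable correlation via a shared patient factor
    mu <- rnorm(p, mean = 3, sd = 0.8)             # per-metabolite baseline
    g <- rnorm(n)
    z <- sqrt(spec$rho) * matrix(g, n, p) +
      sqrt(1 - spec$rho) * matrix(rnorm(n * p), n, p)
    logc <- sweep(z, 2, mu, `+`)
    conc <- exp(logc)
    colnames(conc) <- if (p <= length(plasma_metabolite_roster))
      plasma_metabolite_roster[seq_len(p)]
    else c(plasma_metabolite_roster,
           sprintf("met_%02d", seq_len(p - length(plasma_metabolite_roster))))
    rownames(conc) <- sprintf("P%03d", seq_len(n))

    zc <- sweep(logc, 2, mu)                       # centred log-concentrations
    pecam <- as.numeric(15 + zc %*% spec$true_beta_pecam +
                          rnorm(n, sd = spec$noise_sd_markers))
    stm <- as.numeric(17 + zc %*% spec$true_beta_stm +
                        rnorm(n, sd = spec$noise_sd_markers))
    pecam <- pmax(pecam, 0.1)
    stm <- pmax(stm, 0.1)

    eta <- as.numeric(zc %*% spec$true_beta_mortality)
    prob <- calibrate_event_prob(eta, spec$n_deaths, spec$mortality_link)
    death <- NULL
    for (try in seq_len(max_tries)) {
      d <- rbinom(n, 1L, prob)
      if (sum(d) == spec$n_deaths) { death <- d; break }
    }
    if (is.null(death))
      abort_fmt("could not generate exactly %d deaths in %d tries; event count may be unachievable",
                spec$n_deaths, max_tries)

    # severity score moderately coupled to the mortality signal, so it
    # discriminates like a real ICU severity score (AUC ~0.75) rather than
    # acting as an oracle
    sofa <- pmin(pmax(round(8 + 1.5 * scale(eta)[, 1] + 1.8 * death +
                              rnorm(n, sd = 2.5)), 0L), 24L)
    shock <- rbinom(n, 1L, plogis(-0.2 + 0.3 * death))
    clinical <- data.frame(
      patient_id = rownames(conc),
      survival30 = ifelse(death == 1L, 0L, 1L),   # 1 = survived 30 days
      death30 = as.integer(death),
      pecam = pecam,
      stm = stm,
      sofa = as.integer(sofa),
      septic_shock = as.integer(shock),
      age = pmax(round(rnorm(n, 71, 10)), 18L),
      sex = sample(c("F", "M"), n, replace = TRUE),
      bmi = round(pmax(rnorm(n, 27, 5), 14), 1),
      stringsAsFactors = FALSE
    )
    cohort <- structure(list(metabolites = conc, clinical = clinical,
                             truth = spec),
                        class = "cohort")
    if (spec$missing_rate > 0 || spec$n_high_missing_features > 0)
      cohort <- plant_missingness(cohort, spec)
    cohort
  })
}

# Calibrate the intercept of the mortality link so E[#deaths] = n_deaths.
calibrate_event_prob <- function(eta, n_deaths, link) {
  n <- length(eta)
  if (link == "logistic") {
    f <- function(a) sum(plogis(a + eta)) - n_deaths
    a <- uniroot(f, c(-50, 50), tol = 1e-10)$root
    plogis(a + eta)
  } else {
    sc <- 0.1 / max(sd(eta), 1e-8)
    f <- function(a) sum(pmin(pmax(a + sc * eta, 0.01), 0.99)) - n_deaths
    a <- uniroot(f, c(-5, 5), tol = 1e-10)$root
    pmin(pmax(a + sc * eta, 0.01), 0.99)
  }
}

#' Plant missing values into a complete cohort
#'
#' Applies a cell-wise missing-completely-at-random mask at
#' `spec$missing_rate`, then forces `spec$n_high_missing_features` randomly
#' chosen metabolites above the 10% per-feature missingness threshold (the
#' regime in which the preprocessing filter must drop them). Under the
#' `"mar"` mechanism the cell mask instead prefers low concentrations.
#'
#' @param cohort a complete `cohort`.
#' @param spec the generating [cohort_spec()] (missing-rate fields are read
#'   from it).
#' @return the cohort with `NA`s planted in `metabolites`.
#' @export
plant_missingness <- function(cohort, spec) {
  m <- cohort$metabolites
  if (anyNA(m)) abort_fmt("plant_missingness expects a complete matrix")
  n <- nrow(m); p <- ncol(m)
  with_seed(derive_seed(spec$seed, "missingness"), {
    if (spec$missing_rate > 0) {
      if (spec$missing_mechanism == "mcar") {
        mask <- matrix(runif(n * p) < spec$missing_rate, n, p)
      } else {
        # low values more likely missing: per-feature rank-based probability
        pr <- apply(m, 2, function(x) rank(-x) / (n + 1))
        pr <- pr / mean(pr) * spec$missing_rate
        mask <- matrix(runif(n * p) < pmin(pr, 0.95), n, p)
      }
      m[mask] <- NA_real_
    }
    if (spec$n_high_missing_features > 0) {
      # features carrying planted effects are exempt from the forced-drop
      # set: reported biomarkers are, by construction, ones that survived QC
      signal <- which(spec$true_beta_mortality != 0 |
                        spec$true_beta_pecam != 0 | spec$true_beta_stm != 0)
      cand <- setdiff(seq_len(p), signal)
      if (length(cand) < spec$n_high_missing_features) cand <- seq_len(p)
      feats <- sample(cand, spec$n_high_missing_features)
      need <- floor(0.10 * n) + 1L   # smallest count strictly above 10%
      for (j in feats) {
        have <- which(is.na(m[, j]))
        extra <- need - length(have)
        if (extra > 0) {
          cand <- setdiff(seq_len(n), have)
          m[sample(cand, extra), j] <- NA_real_
        }
      }
    }
    if (any(rowSums(!is.na(m)) == 0))
      abort_fmt("missingness mask removed an entire patient row")
    cohort$metabolites <- m
    cohort
  })
}

#' Write a cohort to plain-text files
#'
#' Writes `metabolites.csv` (patient_id plus one column per metabolite, empty
#' cell = missing), `clinical.csv`, and `truth.json` (the generating spec)
#' under `dir`.
#'
#' @param cohort a `cohort`.
#' @param dir output directory, created if needed.
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  met <- data.frame(patient_id = rownames(cohort$metabolites),
                    cohort$metabolites, check.names = FALSE)
  fm <- file.path(dir, "metabolites.csv")
  fc <- file.path(dir, "clinical.csv")
  ft <- file.path(dir, "truth.json")
  write.csv(met, fm, row.names = FALSE, na = "")
  write.csv(cohort$clinical, fc, row.names = FALSE, na = "")
  if (!is.null(cohort$truth))
    jsonlite::write_json(unclass(cohort$truth), ft, auto_unbox = TRUE,
                         digits = NA)
  invisible(c(metabolites = fm, clinical = fc, truth = ft))
}

#' Read a cohort from CSV files
#'
#' @param metabolites_csv path to the patient x metabolite table (empty cell =
#'   missing).
#' @param clinical_csv path to the clinical table.
#' @return a `cohort` (without ground truth).
#' @export
read_cohort <- function(metabolites_csv, clinical_csv) {
  met <- read.csv(metabolites_csv, check.names = FALSE,
                  stringsAsFactors = FALSE)
  clin <- read.csv(clinical_csv, stringsAsFactors = FALSE)
  m <- as.matrix(met[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- met[[1]]
  if (nrow(m) != nrow(clin))
    abort_fmt("metabolite matrix has %d rows but clinical table has %d",
              nrow(m), nrow(clin))
  structure(list(metabolites = m, clinical = clin, truth = NULL),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic-style cohort: %d patients x %d metabolites (%d missing cells)\n",
              nrow(x$metabolites), ncol(x$metabolites),
              sum(is.na(x$metabolites))))
  if ("death30" %in% names(x$clinical))
    cat(sprintf("  30-day deaths: %d\n", sum(x$clinical$death30)))
  invisible(x)
}
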