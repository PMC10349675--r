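#' Specification of a synthetic study world
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object so downstream parameter-recovery tests can state their world in a
#' single place.  Defaults describe a modest screening study: a few hundred
#' users rating items generated from a low-rank latent-factor model, a
#' balanced two-class post corpus, and a two-group actigraphy cohort with a
#' diurnal activity rhythm.
#'
#' @param seed integer seed; the same seed yields bit-identical output from
#'   every generator.
#' @param n_users,n_items rating-matrix dimensions.
#' @param n_factors latent dimension of the rating model.
#' @param noise_sd standard deviation of the Gaussian rating noise, on the
#'   1--5 rating scale.
#' @param density fraction of user-item cells observed, in (0, 1].
#' @param n_features,n_informative shape of the labelled feature table;
#'   `n_informative <= n_features`.
#' @param n_docs,vocab_size number of documents and vocabulary size of the
#'   labelled corpus.
#' @param signal_strength multiplicative boost of signal-word probability in
#'   the positive corpus class (0 = null world).
#' @param n_subjects,n_days actigraphy cohort size and days of wear per
#'   subject (one-minute epochs).
#' @return An object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(seed = 1, n_users = 50, n_items = 40)
#' r <- gen_ratings(spec)
#' dim(r$matrix)
#' @export
synthetic_spec <- function(seed = 1L,
                           n_users = 200L, n_items = 150L, n_factors = 5L,
                           noise_sd = 0.5, density = 0.2,
                           n_features = 30L, n_informative = 5L,
                           n_docs = 200L, vocab_size = 500L,
                           signal_strength = 3,
                           n_subjects = 20L, n_days = 7L) {
  spec <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_users = check_count(n_users, "n_users"),
    n_items = check_count(n_items, "n_items"),
    n_factors = check_count(n_factors, "n_factors"),
    noise_sd = check_number(noise_sd, "noise_sd", lower = 0),
    density = check_number(density, "density", lower = 0, upper = 1,
                           open_lower = TRUE),
    n_features = check_count(n_features, "n_features"),
    n_informative = check_count(n_informative, "n_informative", min = 0L),
    n_docs = check_count(n_docs, "n_docs"),
    vocab_size = check_count(vocab_size, "vocab_size"),
    signal_strength = check_number(signal_strength, "signal_strength",
                                   lower = 0),
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_days = check_count(n_days, "n_days")
  )
  if (spec$n_informative > spec$n_features) {
    stop_field("n_informative", "must not exceed n_features")
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:",
      sprintf("%d users x %d items (rank %d, density %.2f),", x$n_users,
              x$n_items, x$n_factors, x$density),
      sprintf("%d docs / vocab %d,", x$n_docs, x$vocab_size),
      sprintf("%d subjects x %d days\n", x$n_subjects, x$n_days))
  invisible(x)
}

#' Generate a latent-factor ratings matrix with known ground truth
#'
#' Ratings are `clip(round(u %*% t(v) + noise), 1, 5)` observed at a random
#' `density` fraction of cells.  The latent factors are returned alongside the
#' sparse matrix so recovery tests can compare against the generating model.
#'
#' @param spec a [synthetic_spec()].
#' @return A `ratings_matrix` (see [ratings_matrix()]) with attributes
#'   `user_factors` and `item_factors` retained as ground truth.
#' @export
gen_ratings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    u <- matrix(stats::rnorm(spec$n_users * spec$n_factors, sd = 1),
                spec$n_users, spec$n_factors)
    v <- matrix(stats::rnorm(spec$n_items * spec$n_factors, sd = 1),
                spec$n_items, spec$n_factors)
    full <- u %*% t(v)
    # map the latent scores onto the 1-5 scale before rounding
    full <- 3 + 1.5 * full / max(1e-12, stats::sd(full))
    n_cells <- spec$n_users * spec$n_items
    n_obs <- max(1L, round(spec$density * n_cells))
    idx <- sample.int(n_cells, n_obs)
    vals <- full[idx] + stats::rnorm(n_obs, sd = spec$noise_sd)
    vals <- pmin(5, pmax(1, round(vals)))
    rows <- ((idx - 1L) %% spec$n_users) + 1L
    cols <- ((idx - 1L) %/% spec$n_users) + 1L
    rm <- ratings_matrix(
      data.frame(user_id = paste0("u", rows), item_id = paste0("i", cols),
                 rating = vals,
                 timestamp = sample.int(1e6, n_obs, replace = TRUE),
                 stringsAsFactors = FALSE),
      scale = c(1, 5), relevance = 4
    )
    attr(rm, "user_factors") <- u
    attr(rm, "item_factors") <- v
    rm
  })
}

#' Generate a transaction database with planted frequent itemsets
#'
#' Each planted pattern is embedded as a subset of at least its stated number
#' of transactions (assigned from the start of the database, overlapping when
#' frequencies sum past `n_transactions`); independent noise items are then
#' appended, so planted supports are lower bounds recoverable by counting.
#'
#' @param n_transactions number of transactions to generate.
#' @param planted_patterns list of `list(items = <character>, freq = <int>)`.
#' @param n_noise_items size of the independent noise-item alphabet (each
#'   noise item joins each transaction with probability 0.2).
#' @param seed integer seed.
#' @return A `transaction_db` (see [transaction_db()]).
#' @export
gen_transactions <- function(n_transactions, planted_patterns = list(),
                             n_noise_items = 0L, seed = 1L) {
  n_transactions <- check_count(n_transactions, "n_transactions")
  n_noise_items <- check_count(n_noise_items, "n_noise_items", min = 0L)
  for (p in planted_patterns) {
    if (is.null(p$items) || is.null(p$freq)) {
      stop_field("planted_patterns", "each pattern needs `items` and `freq`")
    }
    if (p$freq > n_transactions) {
      stop_field("planted_patterns",
                 sprintf("frequency %d exceeds n_transactions %d",
                         p$freq, n_transactions))
    }
  }
  with_seed(seed, {
    tx <- replicate(n_transactions, character(0), simplify = FALSE)
    for (p in planted_patterns) {
      slots <- sample.int(n_transactions, p$freq)
      for (s in slots) tx[[s]] <- union(tx[[s]], p$items)
    }
    if (n_noise_items > 0L) {
      noise <- paste0("n", seq_len(n_noise_items))
      for (t in seq_len(n_transactions)) {
        keep <- noise[stats::runif(n_noise_items) < 0.2]
        tx[[t]] <- union(tx[[t]], keep)
      }
    }
    transaction_db(tx)
  })
}

#' Generate a balanced labelled corpus with planted signal words
#'
#' Documents are multinomial bags-of-words over a synthetic vocabulary
#' `w1..wV`.  The positive ("depressed") class boosts a recorded set of signal
#' words by `1 + signal_strength`; at `signal_strength = 0` the two
#' class-conditional distributions are identical.
#'
#' @param spec a [synthetic_spec()].
#' @param n_signal number of signal words (must satisfy
#'   `vocab_size > 2 * n_signal`).
#' @param doc_length mean document length (Poisson, floored at 3 tokens).
#' @return A list of class `labelled_corpus`: `text` (character), `label`
#'   (factor `neg`/`pos`), `signal_words` (character ground truth).
#' @export
gen_corpus <- function(spec, n_signal = 10L, doc_length = 40) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_signal <- check_count(n_signal, "n_signal")
  if (spec$vocab_size <= 2L * n_signal) {
    stop_field("vocab_size", "must exceed twice the signal word count")
  }
  with_seed(spec$seed + 1L, {
    vocab <- paste0("w", seq_len(spec$vocab_size))
    signal <- vocab[seq_len(n_signal)]
    base <- rep(1, spec$vocab_size)
    p_neg <- base / sum(base)
    boost <- base
    boost[seq_len(n_signal)] <- 1 + spec$signal_strength
    p_pos <- boost / sum(boost)
    n_pos <- spec$n_docs %/% 2L
    labels <- factor(rep(c("neg", "pos"), c(spec$n_docs - n_pos, n_pos)),
                     levels = c("neg", "pos"))
    text <- vapply(seq_len(spec$n_docs), function(d) {
      len <- max(3L, stats::rpois(1, doc_length))
      p <- if (labels[d] == "pos") p_pos else p_neg
      paste(sample(vocab, len, replace = TRUE, prob = p), collapse = " ")
    }, character(1))
    structure(list(text = text, label = labels, signal_words = signal),
              class = "labelled_corpus")
  })
}

#' Generate a two-group actigraphy bundle with a diurnal rhythm
#'
#' Each subject gets a per-minute activity series over `n_days` days:
#' a baseline plus a daytime sinusoid, with Gaussian noise, truncated at zero.
#' Condition-group subjects have their daytime signal attenuated by
#' `attenuation`, the planted group effect that recovery tests estimate from
#' daytime group means.  A scores table mirrors the clinical-metadata schema
#' of actigraphy depression studies (patient number, days of measurement,
#' gender, age group, affective-disorder type, melancholia, inpatient status,
#' marriage, work status, MADRS at start and stop).
#'
#' @param spec a [synthetic_spec()]; `n_subjects` is split evenly between
#'   control and condition groups (condition gets the extra subject when odd).
#' @param attenuation fraction by which condition daytime activity is reduced,
#'   in \[0, 1\]; 0 is the null world.
#' @return A list of class `actigraphy_bundle`: `records` (named list of
#'   per-subject data frames with columns `timestamp`, `date`, `activity`),
#'   `scores` (data frame), `groups` (named group vector).
#' @export
gen_actigraphy <- function(spec, attenuation = 0.5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  attenuation <- check_number(attenuation, "attenuation", lower = 0, upper = 1)
  with_seed(spec$seed + 2L, {
    n <- spec$n_subjects
    n_cond <- ceiling(n / 2)
    groups <- rep(c("condition", "control"), c(n_cond, n - n_cond))
    ids <- sprintf("%s_%d", ifelse(groups == "condition", "condition",
                                   "control"),
                   stats::ave(seq_len(n), groups, FUN = seq_along))
    minutes <- spec$n_days * 1440L
    minute_of_day <- (seq_len(minutes) - 1L) %% 1440L
    hour <- minute_of_day / 60
    day <- (seq_len(minutes) - 1L) %/% 1440L
    is_day <- hour >= 8 & hour < 20
    # daytime half-sinusoid peaking at 14:00, zero overnight
    shape <- ifelse(is_day, sin(pi * (hour - 8) / 12), 0)
    origin <- as.POSIXct("2026-03-01 00:00:00", tz = "UTC")
    stamps <- format(origin + 60 * (seq_len(minutes) - 1L),
                     "%Y-%m-%d %H:%M:%S")
    dates <- substr(stamps, 1, 10)
    records <- stats::setNames(vector("list", n), ids)
    for (s in seq_len(n)) {
      level <- 30 + 250 * shape
      if (groups[s] == "condition") {
        level[is_day] <- level[is_day] * (1 - attenuation)
      }
      act <- pmax(0, round(level + stats::rnorm(minutes, sd = 15)))
      records[[s]] <- data.frame(timestamp = stamps, date = dates,
                                 activity = act, stringsAsFactors = FALSE)
    }
    is_cond <- groups == "condition"
    scores <- data.frame(
      number = ids,
      days = spec$n_days,
      gender = sample(c(1L, 2L), n, replace = TRUE),
      age = sample(c("20-24", "25-29", "30-34", "35-39", "40-44",
                     "45-49", "50-54"), n, replace = TRUE),
      afftype = ifelse(is_cond, sample(c(1L, 2L, 3L), n, replace = TRUE), NA),
      melanch = ifelse(is_cond, sample(c(1L, 2L), n, replace = TRUE), NA),
      inpatient = ifelse(is_cond, sample(c(1L, 2L), n, replace = TRUE), NA),
      marriage = sample(c(1L, 2L), n, replace = TRUE),
      work = sample(c(1L, 2L), n, replace = TRUE),
      madrs1 = ifelse(is_cond, sample(18:30, n, replace = TRUE), 0L),
      madrs2 = ifelse(is_cond, sample(12:26, n, replace = TRUE), 0L),
      stringsAsFactors = FALSE
    )
    structure(list(records = records, scores = scores,
                   groups = stats::setNames(groups, ids)),
              class = "actigraphy_bundle")
  })
}

#' Generate a labelled feature table with known informative columns
#'
#' Features are standard normal; binary labels follow a logistic model whose
#' nonzero coefficients sit only on the first `n_informative` (shuffled)
#' columns.  The informative indices are recorded so selector-recovery tests
#' have ground truth.
#'
#' @param n_samples,n_features table shape.
#' @param n_informative number of label-relevant columns
#'   (`<= n_features`; 0 gives a pure-noise null world).
#' @param seed integer seed.
#' @param effect_size absolute logistic coefficient on informative columns;
#'   the default 2 is a strong, clearly recoverable signal.
#' @return A list of class `labelled_features`: `x` (matrix), `y` (integer
#'   0/1), `informative` (integer column indices).
#' @export
gen_feature_table <- function(n_samples, n_features, n_informative,
                              seed = 1L, effect_size = 2) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  n_features <- check_count(n_features, "n_features")
  n_informative <- check_count(n_informative, "n_informative", min = 0L)
  effect_size <- check_number(effect_size, "effect_size", lower = 0)
  if (n_informative > n_features) {
    stop_field("n_informative", "must not exceed n_features")
  }
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    colnames(x) <- paste0("f", seq_len(n_features))
    informative <- sort(sample.int(n_features, n_informative))
    eta <- if (n_informative > 0L) {
      beta <- effect_size * sample(c(-1, 1), n_informative, replace = TRUE)
      drop(x[, informative, drop = FALSE] %*% beta)
    } else {
      rep(0, n_samples)
    }
    y <- as.integer(stats::runif(n_samples) < stats::plogis(eta))
    structure(list(x = x, y = y, informative = informative),
              class = "labelled_features")
  })
}
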