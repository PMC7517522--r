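#' Read and write stimulus sequences
#'
#' Plain-text stimulus files carry one sequence per line as alphabet
#' characters (`"0101"`); CSV files carry columns `trial, symbol` with a
#' mandatory header. Invalid characters are reported with their line and
#' column.
#'
#' @param path File path.
#' @param format `"txt"`, `"csv"`, or `"auto"` (by extension).
#' @param ab The [alphabet()].
#' @return `read_sequence()`: integer 0-based sequence (the first line of a
#'   multi-line txt file).
#' @export
read_sequence <- function(path, format = c("auto", "txt", "csv"),
                          ab = binary_alphabet()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  if (format == "csv") {
    d <- utils::read.csv(path, colClasses = "character")
    if (!all(c("trial", "symbol") %in% names(d)))
      stop("sequence CSV needs 'trial' and 'symbol' columns")
    d <- d[order(as.integer(d$trial)), , drop = FALSE]
    idx <- match(trimws(d$symbol), ab$symbols)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop(sprintf("invalid symbol '%s' at data row %d", d$symbol[bad], bad))
    }
    return(idx - 1L)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(integer(0))
  line <- trimws(lines[[1]])
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  idx <- match(chars, ab$symbols)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("invalid symbol '%s' at line 1, column %d",
                 chars[bad], bad))
  }
  idx - 1L
}

#' @param x Integer 0-based sequence.
#' @rdname read_sequence
#' @export
write_sequence <- function(x, path, format = c("auto", "txt", "csv"),
                           ab = binary_alphabet()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  if (format == "csv") {
    d <- data.frame(trial = seq_along(x), symbol = ab$symbols[x + 1L])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(seq_to_string(x, ab), path)
  }
  invisible(path)
}

# 17 significant digits guarantee a bit-exact double round-trip.
fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write prediction traces
#'
#' A single-observer trace serializes as CSV with columns
#' `trial, stimulus_symbol, predicted_symbol, p_emit_0, p_emit_1` (the
#' predicted column empty for emission-only traces); ensembles as a wide
#' matrix CSV `trial, stimulus_symbol, clone_1..clone_n, freq_0, freq_1`.
#' Probabilities are written with 17 significant digits so round-trips are
#' exact to the double representation.
#'
#' @param trace A `"prediction_trace"` or `"ensemble_trace"`.
#' @param path File path.
#' @return `read_trace()`: a `"prediction_trace"` (without the spec, which
#'   is not serialized).
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "ensemble_trace")) {
    n <- trace$n_clones
    d <- data.frame(trial = seq_along(trace$stimulus),
                    stimulus_symbol = trace$stimulus)
    for (i in seq_len(n)) d[[paste0("clone_", i)]] <- trace$prediction_matrix[i, ]
    for (s in seq_len(ncol(trace$empirical_freqs)))
      d[[paste0("freq_", s - 1L)]] <- fmt17(trace$empirical_freqs[, s])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(trace, "prediction_trace"))
  d <- data.frame(trial = seq_along(trace$stimulus),
                  stimulus_symbol = trace$stimulus,
                  predicted_symbol = if (is.null(trace$predictions))
                    rep("", length(trace$stimulus)) else trace$predictions)
  for (s in seq_len(ncol(trace$emission_probs)))
    d[[paste0("p_emit_", s - 1L)]] <- fmt17(trace$emission_probs[, s])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  need <- c("trial", "stimulus_symbol", "predicted_symbol")
  if (!all(need %in% names(d)))
    stop("trace CSV needs columns: ", paste(need, collapse = ", "))
  pcols <- grep("^p_emit_", names(d), value = TRUE)
  probs <- as.matrix(d[, pcols, drop = FALSE])
  preds <- d$predicted_symbol
  has_preds <- !all(is.na(preds) | preds == "")
  prediction_trace(d$stimulus_symbol, probs,
                   predictions = if (has_preds) as.integer(preds))
}

#' Read and write Markov models as JSON
#'
#' A model file is JSON with fields `order`, `alphabet` (the symbol list)
#' and `emission`, the table keyed by context string (most recent symbol
#' last; `""` for order 0).
#'
#' @param model A [markov_model()].
#' @param path File path.
#' @return `read_model()`: a [markov_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "markov_model"))
  em <- lapply(seq_len(nrow(model$emission)),
               function(i) unname(model$emission[i, ]))
  names(em) <- rownames(model$emission)
  # an order-0 model's single context is the empty string
  obj <- list(order = model$order, alphabet = model$alphabet$symbols,
              emission = em)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ab <- alphabet(obj$alphabet)
  ctx <- context_strings(obj$order, ab)
  em <- if (obj$order == 0L)
    matrix(unlist(obj$emission), nrow = 1L)  # single (empty-string) context
  else do.call(rbind, obj$emission[ctx])
  markov_model(obj$order, em, ab)
}

#' Serialize an order posterior to JSON
#'
#' @param post An [order_posterior()].
#' @param path File path.
#' @export
write_order_posterior <- function(post, path) {
  stopifnot(inherits(post, "order_posterior"))
  obj <- list(r_max = post$r_max, alpha = post$alpha, beta = post$beta,
              gamma = post$gamma, z_prior = post$z_prior,
              log_prior = as.list(post$log_prior),
              log_evidence = as.list(post$log_evidence),
              log_posterior = as.list(post$log_posterior),
              map_order = post$map_order)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an experiment configuration (JSON or YAML)
#'
#' Configurations have a `stimulus` block (`order`, `length`, and a
#' `model_seed` or `model_file`), an `observers` block (list of strategy
#' specs with seeds and optional clone counts), and an `inference` block
#' (grids, `r_max`, tolerances). A single top-level `seed` spawns all
#' component seeds not given explicitly.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return The configuration as a nested list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  }
  if (is.null(cfg$stimulus)) stop("config is missing the 'stimulus' block")
  cfg
}

# Build an observer_spec from a config entry.
spec_from_config <- function(entry) {
  strategy <- entry$strategy
  if (is.null(strategy)) stop("observer entry is missing 'strategy'")
  if (strategy == "glm")
    observer_spec("glm", window = entry$window %||% 1L,
                  ridge = entry$ridge %||% 1e-4)
  else
    observer_spec(strategy, alpha = entry$alpha %||% 1,
                  beta = entry$beta %||% 1, gamma = entry$gamma %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the deterministic fixture bundle
#'
#' Writes a small reproducible bundle used by the test suite: an order-2
#' model (JSON), a length-300 stimulus (txt), one simulated prediction trace
#' per strategy (CSV), and the per-strategy log-likelihoods of each trace
#' under its own generating spec computed by the slow per-trial reference
#' path (JSON). Identical seeds give byte-identical bundles.
#'
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
make_fixtures <- function(seed = 20260101L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 5L)
  model <- sample_markov_model(2L, concentration = 1, seed = seeds[1])
  stim <- generate_stimulus(model, 300L, seed = seeds[2])
  paths <- list(model = file.path(dir, "model.json"),
                stimulus = file.path(dir, "stimulus.txt"),
                expected = file.path(dir, "expected_logliks.json"))
  write_model(model, paths$model)
  write_sequence(stim, paths$stimulus)
  specs <- list(
    ngram_argmax = observer_spec("ngram_argmax", alpha = 2, beta = 1,
                                 gamma = 0.5),
    ngram_average = observer_spec("ngram_average", alpha = 1, beta = 1,
                                  gamma = 0.5),
    glm = observer_spec("glm", window = 2L))
  expected <- list()
  r_max_fix <- 4L                       # keeps the reference path quick
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    trace <- simulate_observer(specs[[i]], stim, seed = seeds[2 + i],
                               r_max = r_max_fix)
    p <- file.path(dir, paste0("trace_", nm, ".csv"))
    write_trace(trace, p)
    paths[[paste0("trace_", nm)]] <- p
    ref <- emission_stream_reference(specs[[i]], stim, r_max = r_max_fix)
    expected[[nm]] <- loglik_from_stream(ref$emission_probs,
                                         trace$predictions)
  }
  expected$r_max <- r_max_fix
  expected$seed <- seed
  jsonlite::write_json(expected, paths$expected, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
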