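#' Finite alphabets and symbol sequences
#'
#' Stimuli are sequences over a small finite alphabet; the binary alphabet
#' `{"0", "1"}` is the default throughout. Internally a sequence is stored as
#' a plain integer vector of 0-based symbol indices; `seq_to_string()` and
#' `string_to_seq()` convert to and from the single-line character form used
#' in stimulus files.
#'
#' @param symbols Character vector of distinct single-token symbols, in order.
#' @return An object of class `"pred_alphabet"` with fields `symbols` and
#'   `size`.
#' @export
alphabet <- function(symbols = c("0", "1")) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L) stop("an alphabet needs at least 2 symbols")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be distinct")
  structure(list(symbols = symbols, size = length(symbols)),
            class = "pred_alphabet")
}

#' @rdname alphabet
#' @export
binary_alphabet <- function() alphabet(c("0", "1"))

#' @param x Integer vector of 0-based symbol indices.
#' @param ab A [alphabet()] object.
#' @rdname alphabet
#' @export
seq_to_string <- function(x, ab = binary_alphabet()) {
  paste(ab$symbols[x + 1L], collapse = "")
}

#' @param s A single string of alphabet characters.
#' @rdname alphabet
#' @export
string_to_seq <- function(s, ab = binary_alphabet()) {
  if (!nzchar(s)) return(integer(0))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(chars, ab$symbols)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("invalid symbol '%s' at position %d", chars[bad], bad))
  }
  idx - 1L
}

# Validate a 0-based symbol sequence against an alphabet size.
check_sequence <- function(x, A) {
  if (length(x) && (anyNA(x) || any(x < 0L | x >= A)))
    stop("sequence contains symbols outside the alphabet")
  as.integer(x)
}

# All length-R context strings, oldest symbol first, in internal index order.
# The internal context index encodes the most recent symbol in the lowest
# base-A digit: index = 1 + sum_j s_{t-j} * A^(j-1).
context_strings <- function(order, ab = binary_alphabet()) {
  A <- ab$size
  if (order == 0L) return("")
  idx <- 0:(A^order - 1L)
  out <- character(length(idx))
  for (j in seq_len(order)) {            # j-th most recent symbol
    digit <- (idx %/% A^(j - 1L)) %% A
    # most-recent-last: digit j occupies string position order - j + 1
    if (j == 1L) out <- ab$symbols[digit + 1L]
    else out <- paste0(ab$symbols[digit + 1L], out)
  }
  out
}

#' Construct an order-R Markov model
#'
#' An order-R Markov model over alphabet `A` is a table of emission
#' probabilities `p(s | c)` for every length-R context `c` (the last R
#' symbols, most recent last). `R = 0` is a biased coin with a single empty
#' context.
#'
#' @param order Markov order `R >= 0`.
#' @param emission Numeric matrix with `size^order` rows (one per context, in
#'   the order given by the internal context indexing) and `size` columns
#'   (one per symbol). Rows must be nonnegative and sum to 1.
#' @param ab The [alphabet()].
#' @return An object of class `"markov_model"`.
#' @export
markov_model <- function(order, emission, ab = binary_alphabet()) {
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  A <- ab$size
  emission <- as.matrix(emission)
  if (nrow(emission) != A^order || ncol(emission) != A)
    stop(sprintf("emission must be a %d x %d matrix", A^order, A))
  if (any(emission < 0)) stop("emission probabilities must be nonnegative")
  if (any(abs(rowSums(emission) - 1) > 1e-12))
    stop("each emission row must sum to 1 (within 1e-12)")
  dimnames(emission) <- list(context_strings(order, ab), ab$symbols)
  structure(list(order = order, alphabet = ab, emission = emission),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("order-%d Markov model over {%s}\n", x$order,
              paste(x$alphabet$symbols, collapse = ", ")))
  print(round(x$emission, 4))
  invisible(x)
}

#' Sample a random order-R Markov model
#'
#' Draws each context's emission vector independently from a symmetric
#' Dirichlet distribution. `concentration = 1` gives emission vectors uniform
#' on the simplex.
#'
#' @inheritParams markov_model
#' @param concentration Positive symmetric-Dirichlet concentration.
#' @param seed Integer seed; the same seed reproduces the same model.
#' @return A [markov_model()].
#' @export
sample_markov_model <- function(order, ab = binary_alphabet(),
                                concentration = 1, seed = 1L) {
  if (order < 0) stop("order must be >= 0")
  if (concentration <= 0) stop("concentration must be positive")
  A <- ab$size
  n_ctx <- A^as.integer(order)
  g <- with_seed(seed, matrix(stats::rgamma(n_ctx * A, shape = concentration),
                              nrow = n_ctx))
  markov_model(order, g / rowSums(g), ab)
}

# Context-chain transition matrix (A^R x A^R) of a markov_model, R >= 1.
context_transition_matrix <- function(model) {
  A <- model$alphabet$size
  R <- model$order
  n <- A^R
  Tm <- matrix(0, n, n)
  for (c in seq_len(n)) {
    nxt <- 1L + (0:(A - 1L)) + A * ((c - 1L) %% A^(R - 1L))
    for (s in seq_len(A)) Tm[c, nxt[s]] <- Tm[c, nxt[s]] + model$emission[c, s]
  }
  Tm
}

# Strong-connectivity test on the positive-probability context graph.
# Returns character() if strongly connected, else the contexts not mutually
# reachable from context 1.
unreachable_contexts <- function(model) {
  R <- model$order
  if (R == 0L) return(character(0))
  adj <- context_transition_matrix(model) > 0
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  # boolean transitive closure by repeated squaring
  steps <- ceiling(log2(max(n, 2)))
  for (i in seq_len(steps)) reach <- (reach %*% reach) > 0
  mutual <- reach[1, ] & reach[, 1]
  context_strings(R, model$alphabet)[!mutual]
}

# Stationary distribution over length-R contexts (damped power iteration;
# damping removes periodicity without changing the fixed point).
stationary_contexts <- function(model, tol = 1e-13, max_iter = 20000L) {
  R <- model$order
  A <- model$alphabet$size
  if (R == 0L) return(1)
  Tm <- context_transition_matrix(model)
  pi0 <- rep(1 / nrow(Tm), nrow(Tm))
  for (i in seq_len(max_iter)) {
    pi1 <- 0.5 * pi0 + 0.5 * drop(pi0 %*% Tm)
    if (max(abs(pi1 - pi0)) < tol) return(pi1 / sum(pi1))
    pi0 <- pi1
  }
  pi0 / sum(pi0)
}

#' Generate a stimulus sequence from a Markov model
#'
#' The initial length-R context is drawn from the model's stationary
#' distribution over contexts (so counts carry no transient bias); if the
#' context chain is not irreducible the initial context is drawn uniformly
#' instead. Subsequent symbols are drawn from the emission probabilities of
#' the current context.
#'
#' @param model A [markov_model()].
#' @param length Number of trials `t >= 0` to generate.
#' @param seed Integer seed.
#' @param burn_in Extra symbols generated and discarded before the returned
#'   sequence (default 0; stationary initialization makes burn-in redundant
#'   for irreducible models).
#' @return Integer vector of 0-based symbols, length `length`.
#' @export
generate_stimulus <- function(model, length, seed = 1L, burn_in = 0L) {
  stopifnot(inherits(model, "markov_model"))
  if (length < 0) stop("length must be >= 0")
  A <- model$alphabet$size
  R <- model$order
  n_total <- as.integer(length) + as.integer(burn_in)
  with_seed(seed, {
    if (R == 0L) {
      ctx <- 1L
      init <- integer(0)
    } else {
      pi_ctx <- if (length(unreachable_contexts(model)) == 0L)
        stationary_contexts(model) else rep(1 / A^R, A^R)
      ctx <- sample.int(A^R, 1L, prob = pi_ctx)
      # decode the context into its R symbols (digit j = j-th most recent)
      init <- integer(R)
      rem <- ctx - 1L
      for (j in seq_len(R)) {         # init[R - j + 1] is j-th most recent
        init[R - j + 1L] <- rem %% A
        rem <- rem %/% A
      }
    }
    out <- integer(n_total)
    u <- stats::runif(n_total)
    for (i in seq_len(n_total)) {
      p <- model$emission[ctx, ]
      s <- findInterval(u[i], cumsum(p), left.open = TRUE)  # 0-based symbol
      s <- min(s, A - 1L)
      out[i] <- s
      if (R > 0L) ctx <- 1L + s + A * ((ctx - 1L) %% A^(R - 1L))
    }
    if (burn_in > 0L) out <- out[-seq_len(burn_in)]
    out
  })
}

#' Count context occurrences in a sequence
#'
#' Overlapping sliding-window counts for every order `R <= max_order`:
#' position `i` (for `i > R`) contributes one count to its length-R context
#' `n(c)` and to the context-plus-symbol count `n(c s_i)`. Windows that would
#' extend before the first trial are skipped, so at order R the context
#' counts total `max(t - R, 0)`.
#'
#' @param x Integer 0-based symbol sequence.
#' @param max_order Largest order to count.
#' @param ab The [alphabet()].
#' @return An object of class `"context_counts"`: a list with `max_order`,
#'   `alphabet`, `t`, and per-order count matrices `ncs[[R + 1]]`
#'   (contexts x symbols, with `n(c)` as `rowSums`).
#' @export
count_contexts <- function(x, max_order, ab = binary_alphabet()) {
  if (max_order < 0) stop("max_order must be >= 0")
  A <- ab$size
  x <- check_sequence(x, A)
  t <- length(x)
  ncs <- vector("list", max_order + 1L)
  for (R in 0:max_order) {
    m <- matrix(0L, A^R, A,
                dimnames = list(context_strings(R, ab), ab$symbols))
    if (t > R) {
      pos <- (R + 1L):t
      k <- rep(1L, length(pos))                 # context index per position
      if (R > 0L) for (j in seq_len(R)) k <- k + x[pos - j] * A^(j - 1L)
      flat <- (k - 1L) * A + x[pos] + 1L        # column-major would differ;
      tab <- tabulate(flat, nbins = A^R * A)    # flat is row-major (ctx, sym)
      m <- matrix(tab[seq_len(A^R * A)], nrow = A^R, byrow = TRUE,
                  dimnames = dimnames(m))
    }
    ncs[[R + 1L]] <- m
  }
  structure(list(max_order = as.integer(max_order), alphabet = ab,
                 t = t, ncs = ncs),
            class = "context_counts")
}

# Accessors: n(c) and n(c s) at a given order, by context string.
counts_nc <- function(counts, R) rowSums(counts$ncs[[R + 1L]])
counts_ncs <- function(counts, R) counts$ncs[[R + 1L]]

#' Conditional entropy of a Markov model
#'
#' Computes `h(R) = H[S_{R+1} | S_1, ..., S_R]` in nats, exactly, from the
#' model's stationary distribution: the expected entropy of the next symbol
#' given the previous `R`. For `R` at or above the model order this is the
#' entropy rate; below it, block marginals of the stationary process are
#' used. Non-ergodic models (context chain not strongly connected) are an
#' error naming the offending contexts.
#'
#' @param model A [markov_model()].
#' @param order Conditioning length `R >= 0`.
#' @return Conditional entropy in nats, in `[0, log(size)]`.
#' @export
conditional_entropy <- function(model, order) {
  stopifnot(inherits(model, "markov_model"))
  if (order < 0) stop("order must be >= 0")
  bad <- unreachable_contexts(model)
  if (length(bad))
    stop("model is not ergodic; unreachable context set: ",
         paste(bad, collapse = ", "))
  A <- model$alphabet$size
  R0 <- model$order
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pi0 <- stationary_contexts(model)
  if (order >= R0)
    return(sum(pi0 * apply(model$emission, 1, ent)))
  # order < R0: joint over (order+1)-blocks from the stationary (R0+1)-words
  R <- as.integer(order)
  nv <- A^(R + 1L)
  pv <- numeric(nv)
  for (c in seq_len(A^R0)) {
    for (s in 0:(A - 1L)) {
      w <- model$emission[c, s + 1L] * pi0[c]
      if (w == 0) next
      v <- 1L + s + A * ((c - 1L) %% A^R)   # last R+1 symbols of (c, s)
      pv[v] <- pv[v] + w
    }
  }
  pu <- numeric(A^R)
  for (v in seq_len(nv)) pu[1L + (v - 1L) %/% A] <-
    pu[1L + (v - 1L) %/% A] + pv[v]
  # H[(R+1)-block] - H[R-block]; the older-R marginal of a stationary block
  # equals the R-block marginal
  keep <- pv > 0
  -sum(pv[keep] * log(pv[keep] / pu[1L + (which(keep) - 1L) %/% A]))
}

#' @describeIn conditional_entropy Conditional entropies for `R = 0..r_max`
#'   as a named numeric vector (the entropy curve `h(R)`).
#' @param r_max Largest order for the curve.
#' @export
entropy_curve <- function(model, r_max) {
  h <- vapply(0:r_max, function(R) conditional_entropy(model, R), numeric(1))
  names(h) <- 0:r_max
  h
}
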