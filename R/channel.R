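#' Parameters of the quaternary sequencing channel
#'
#' The simulator treats each transmitted symbol as queued in a memoryless
#' state machine. Two parameterizations are supported:
#'
#' * **mode `"pmut"`** (the evaluation channel): per queued symbol, a round
#'   is a correct transmission C with probability `1 - p_mut` or one of the
#'   error events S (substitution to one of the three other bases,
#'   uniformly), I (a uniform random symbol is emitted and the symbol stays
#'   queued) or D (the symbol is dropped), each with probability
#'   `p_mut / 3`. An I round repeats, so any number of insertions can
#'   precede a symbol.
#' * **mode `"matrix"`**: insertion probability `p_i`, deletion probability
#'   `p_d`, and with probability `p_t = 1 - p_i - p_d` the symbol passes a
#'   substitution channel with column-stochastic matrix `S`
#'   (`S[r, t] = P(receive r | sent t)`).
#'
#' Context lengths for embedding are drawn as the nearest non-negative
#' integer of a normal draw with mean `mu_l` and standard deviation
#' `sigma_l`; context symbols are uniform over A, C, G, T.
#'
#' @param p_mut per-symbol probability of any error event (mode `"pmut"`).
#' @param S 4 x 4 column-stochastic substitution matrix (mode `"matrix"`).
#' @param p_i,p_d insertion and deletion probabilities (mode `"matrix"`).
#' @param mu_l,sigma_l context length distribution (defaults 50 and 5).
#' @return object of class `channel_params`.
#' @export
channel_params <- function(p_mut = NULL, S = NULL, p_i = NULL, p_d = NULL,
                           mu_l = 50, sigma_l = 5) {
  stopifnot(mu_l >= 0, sigma_l >= 0)
  if (!is.null(p_mut)) {
    stopifnot(p_mut >= 0, p_mut < 1)
    out <- list(mode = "pmut", p_mut = p_mut, mu_l = mu_l, sigma_l = sigma_l)
  } else {
    if (is.null(S) || is.null(p_i) || is.null(p_d)) {
      stop("either p_mut or (S, p_i, p_d) must be given")
    }
    .check_stochastic(S)
    stopifnot(p_i >= 0, p_d >= 0, p_i + p_d < 1)
    out <- list(mode = "matrix", S = S, p_i = p_i, p_d = p_d,
                mu_l = mu_l, sigma_l = sigma_l)
  }
  structure(out, class = "channel_params")
}

#' Symmetric substitution matrix
#'
#' Column-stochastic 4 x 4 matrix with a single error parameter: a sent
#' base is received unchanged with probability `1 - e` and as each of the
#' other three bases with probability `e / 3` (Jukes-Cantor style).
#'
#' @param e total substitution probability, in \[0, 1\].
#' @export
uniform_substitution <- function(e) {
  stopifnot(e >= 0, e <= 1)
  m <- matrix(e / 3, 4L, 4L)
  diag(m) <- 1 - e
  m
}

#' Embed a barcode in random context
#'
#' `t = t_pre . b . t_post` with independent context lengths
#' `max(0, round(N(mu_l, sigma_l)))` and uniform random context symbols.
#' The offset `delta = |t_pre|` is the true barcode start.
#'
#' @param b barcode DNA string.
#' @param params a `channel_params`.
#' @return list with `t` (DNA string) and `delta` (integer offset; the
#'   barcode occupies `t[delta + 1 .. delta + N]`, 1-based).
#' @export
embed_barcode <- function(b, params) {
  stopifnot(inherits(params, "channel_params"))
  len <- function() max(0L, as.integer(round(stats::rnorm(1L, params$mu_l, params$sigma_l))))
  npre <- len()
  npost <- len()
  ctx <- function(n) if (n > 0L) paste(c("A", "C", "G", "T")[sample.int(4L, n, TRUE)],
                                       collapse = "") else ""
  list(t = paste0(ctx(npre), b, ctx(npost)), delta = npre)
}

#' Transmit a sequence through the indel channel
#'
#' Simulates the per-symbol state machine of [channel_params()] and records
#' an event log: for each transmit position, zero or more insertion events
#' I followed by exactly one of C (emitted unchanged), S (emitted
#' substituted) or D (deleted). The log replays to the received sequence
#' exactly (see [replay_events()]).
#'
#' @param t transmitted DNA string.
#' @param params a `channel_params`.
#' @return list with `r` (received DNA string) and `events` (data.frame
#'   with columns `pos` (1-based transmit position), `type` (`"I"`, `"C"`,
#'   `"S"`, `"D"`) and `sym` (emitted base, `NA` for D)).
#' @export
transmit <- function(t, params) {
  stopifnot(inherits(params, "channel_params"))
  tv <- dna_map(t)
  L <- length(tv)
  if (params$mode == "pmut") {
    qe <- params$p_mut / 3
    n_ins <- if (qe > 0) stats::rgeom(L, 1 - qe) else integer(L)
    u <- stats::runif(L) * (1 - qe)
    del <- u < qe
    sub <- !del & u < 2 * qe
    out_sym <- tv
    if (any(sub)) {
      # substitution always changes the base: uniform over the other three
      shift <- sample.int(3L, sum(sub), replace = TRUE)
      out_sym[sub] <- (tv[sub] + shift) %% 4L
    }
  } else {
    p_i <- params$p_i; p_d <- params$p_d
    n_ins <- if (p_i > 0) stats::rgeom(L, 1 - p_i) else integer(L)
    del <- stats::runif(L) < p_d / (1 - p_i)
    out_sym <- tv
    for (b in 0:3) {
      idx <- which(tv == b & !del)
      if (length(idx)) {
        out_sym[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                   prob = params$S[, b + 1L]) - 1L
      }
    }
    sub <- !del & out_sym != tv
  }
  total_ins <- sum(n_ins)
  ins_pos <- rep.int(seq_len(L), n_ins)
  ins_sym <- if (total_ins > 0L) sample.int(4L, total_ins, TRUE) - 1L else integer(0)
  fin_type <- ifelse(del, "D", ifelse(sub, "S", "C"))
  ev <- data.frame(
    pos = c(ins_pos, seq_len(L)),
    type = c(rep.int("I", total_ins), fin_type),
    sym = c(ins_sym, ifelse(del, NA_integer_, out_sym))
  )
  ev <- ev[order(ev$pos, ev$type != "I"), , drop = FALSE]
  rownames(ev) <- NULL
  emitted <- ev$sym[ev$type != "D"]
  list(r = if (length(emitted)) dna_unmap(emitted) else "", events = ev)
}

#' Replay an event log
#'
#' Reconstructs the received sequence from a [transmit()] event log;
#' `replay_events(transmit(t, p)$events)` equals the emitted read.
#'
#' @param events event-log data.frame from [transmit()].
#' @return received DNA string.
#' @export
replay_events <- function(events) {
  emitted <- events$sym[events$type != "D"]
  if (length(emitted) == 0L) return("")
  dna_unmap(emitted)
}

#' Probability of a defective barcode
#'
#' Probability that at least one channel error event (S, I or D) hits a
#' barcode of length `N`: `1 - (1 - p_mut)^N`.
#'
#' @param p_mut per-symbol error probability.
#' @param N barcode length.
#' @export
pr_defective <- function(p_mut, N) {
  stopifnot(p_mut >= 0, p_mut <= 1, N >= 1)
  1 - (1 - p_mut)^N
}

#' Generate a batch of synthetic reads with ground truth
#'
#' Draws barcodes uniformly from the set, embeds each in random context and
#' transmits it through the channel. With `defective_only = TRUE` the
#' transmission (not the embedding) is resampled until at least one error
#' event falls on a barcode position, conditioning the batch on the
#' defective event whose probability is [pr_defective()]; error-free reads
#' carry no information about decoding failure, so the error-estimation
#' harness only simulates defective ones.
#'
#' @param set a `barcode_set` (non-empty).
#' @param params a `channel_params`.
#' @param n_reads number of reads.
#' @param defective_only condition every read on >= 1 barcode error event.
#' @return list with `reads` (named character vector), `truth` (data.frame:
#'   `read_id`, `index` (true message index), `delta`, `t_len`, `r_len`,
#'   `defective`) and `events` (list of event logs).
#' @export
make_batch <- function(set, params, n_reads, defective_only = FALSE) {
  stopifnot(inherits(set, "barcode_set"), inherits(params, "channel_params"))
  if (length(set$barcodes) == 0L) stop("empty barcode set")
  n_reads <- as.integer(n_reads)
  if (defective_only) {
    errorless <- (params$mode == "pmut" && params$p_mut == 0) ||
      (params$mode == "matrix" && params$p_i == 0 && params$p_d == 0 &&
         all(diag(params$S) == 1))
    if (errorless) stop("conditioning impossible: channel produces no errors")
  }
  N <- set$config$N
  reads <- character(n_reads)
  events <- vector("list", n_reads)
  truth <- data.frame(read_id = character(n_reads), index = integer(n_reads),
                      delta = integer(n_reads), t_len = integer(n_reads),
                      r_len = integer(n_reads), defective = logical(n_reads))
  picks <- if (n_reads > 0L) sample.int(length(set$barcodes), n_reads, replace = TRUE)
           else integer(0)
  for (i in seq_len(n_reads)) {
    b <- set$barcodes[picks[i]]
    emb <- embed_barcode(b, params)
    span <- (emb$delta + 1L):(emb$delta + N)
    repeat {
      tx <- transmit(emb$t, params)
      defect <- any(tx$events$type != "C" & tx$events$pos %in% span)
      if (!defective_only || defect) break
    }
    id <- sprintf("read%06d", i)
    reads[i] <- tx$r
    events[[i]] <- tx$events
    truth[i, ] <- list(id, set$indices[picks[i]], emb$delta,
                       nchar(emb$t), nchar(tx$r), defect)
  }
  names(reads) <- truth$read_id
  list(reads = reads, truth = truth, events = events)
}
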