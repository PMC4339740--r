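#' Decoder HMM parameters
#'
#' The decoding HMM tracks the drift (insertions minus deletions) before
#' each transmitted symbol as its hidden state. Its parameters are the
#' substitution matrix `S`, insertion and deletion probabilities `p_i` and
#' `p_d`, the maximal number `I` of leading insertions per observable (the
#' HMM truncates what the channel leaves unbounded), and the half-width
#' `Delta` of the drift window used to prune states in the symbol-wise
#' pass.
#'
#' @param S 4 x 4 column-stochastic substitution matrix.
#' @param p_i,p_d insertion/deletion probabilities, `p_i + p_d < 1`.
#' @param I maximal leading insertions per observable (>= 1).
#' @param Delta drift-window half-width (default 10).
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(S, p_i, p_d, I = 2L, Delta = 10L) {
  .check_stochastic(S)
  stopifnot(p_i >= 0, p_d >= 0, p_i + p_d < 1, I >= 1, Delta >= 1)
  structure(list(S = S, p_i = p_i, p_d = p_d, I = as.integer(I),
                 Delta = as.integer(Delta)),
            class = "hmm_params")
}

#' @rdname hmm_params
#' @param p_mut per-symbol error probability of the evaluation channel; the
#'   matched HMM uses `p_i = p_d = p_mut / 3` and a symmetric substitution
#'   matrix with conditional substitution probability
#'   `(p_mut / 3) / (1 - 2 p_mut / 3)` (a substitution happens with
#'   probability `p_mut / 3` per symbol, conditioned on the symbol being
#'   emitted at all).
#' @export
hmm_from_pmut <- function(p_mut, I = 2L, Delta = 10L) {
  stopifnot(p_mut >= 0, p_mut < 1)
  q <- p_mut / 3
  hmm_params(S = uniform_substitution(q / (1 - 2 * q)),
             p_i = q, p_d = q, I = I, Delta = Delta)
}

#' Insertion-length weights of the observable model
#'
#' `alpha(0) = 1` and `alpha(l') = p_i^l' / (1 - p_i^I)` for
#' `1 <= l' <= I`: the relative weight of `l'` random leading insertions in
#' an observable. Together with the deletion/transmission split these
#' weights determine the (renormalized) observable-length distribution
#' [transition_distribution()].
#'
#' @param p_i insertion probability, `0 <= p_i < 1`.
#' @param I maximal leading insertions.
#' @return numeric vector `alpha[l' + 1]`, `l' = 0..I`.
#' @export
insertion_weights <- function(p_i, I) {
  stopifnot(p_i >= 0, p_i < 1, I >= 1)
  lp <- 1:I
  c(1, p_i^lp / (1 - p_i^I))
}

#' Observable-length distribution p(l)
#'
#' Probability that the observable emitted for one transmitted symbol has
#' length `l`, for `l = 0..I+1`: `l` leading insertions with the symbol
#' deleted, or `l - 1` leading insertions with the symbol emitted. The raw
#' weights `alpha(l) p_d + alpha(l-1) p_t` (with `p_t = 1 - p_i - p_d`) do
#' not sum to one under the truncation at `I`, so they are renormalized;
#' the same constant scales the emission probabilities [emission_QS()] so
#' that the HMM stays a proper probability model.
#'
#' @inheritParams insertion_weights
#' @param p_d deletion probability.
#' @return numeric vector `p[l + 1]`, `l = 0..I+1`, summing to 1.
#' @export
transition_distribution <- function(p_i, p_d, I) {
  stopifnot(p_i + p_d < 1)
  alpha <- insertion_weights(p_i, I)
  p_t <- 1 - p_i - p_d
  raw <- c(alpha, 0) * p_d + c(0, alpha) * p_t
  raw / sum(raw)
}

# all derived HMM constants: q0, per-length deletion/substitution emission
# coefficients (renormalized), p(l)
.hmm_tables <- function(H) {
  I <- H$I
  alpha <- insertion_weights(H$p_i, I)
  p_t <- 1 - H$p_i - H$p_d
  alpha_ext <- c(alpha, 0)                    # alpha(I+1) = 0
  raw <- alpha_ext * H$p_d + c(0, alpha) * p_t
  Z <- sum(raw)
  lv <- 1:(I + 1L)
  list(I = I,
       p = raw / Z,
       q0 = H$p_d / Z,
       del_c = alpha_ext[lv + 1L] * H$p_d / (4^lv * Z),
       sub_c = alpha * p_t / (4^(lv - 1L) * Z))
}

#' Emission probability of the barcode HMM
#'
#' Joint probability `Q^S(l, r_l, t)` of a state transition of drift
#' increment `l - 1` together with a specific observable of length `l`
#' ending in read symbol `r_l`, given transmitted symbol `t`:
#' `(alpha(l)/4^l) p_d + (alpha(l-1)/4^(l-1)) p_t S(r_l, t)`, scaled by the
#' normalization constant of [transition_distribution()]. `l = 0` is the
#' bare deletion (empty observable). Summing over all `4^l` observables of
#' length `l` recovers `p(l)`.
#'
#' @param l observable length, `0 <= l <= I + 1`.
#' @param r_last last (emitted) read symbol over Z4; ignored for `l = 0`.
#' @param t_sym transmitted symbol over Z4.
#' @param H an `hmm_params`.
#' @return numeric probability.
#' @export
emission_QS <- function(l, r_last, t_sym, H) {
  .emission(l, r_last, t_sym, H, H$S)
}

#' @rdname emission_QS
#' @param w_sym watermark symbol over Z4 (plays the role of the transmitted
#'   symbol in the boundary-estimation HMM).
#' @param E effective substitution matrix from [effective_substitution()];
#'   `Q^E` is `Q^S` with `S` replaced by `E`.
#' @export
emission_QE <- function(l, r_last, w_sym, E, H) {
  .emission(l, r_last, w_sym, H, E)
}

.emission <- function(l, r_last, t_sym, H, M) {
  tab <- .hmm_tables(H)
  if (l < 0L || l > H$I + 1L) stop("observable length l out of range 0..I+1")
  if (l == 0L) return(tab$q0)
  tab$del_c[l] + tab$sub_c[l] * M[r_last + 1L, t_sym + 1L]
}

# substitution-matrix values of read positions for one label symbol:
# gv[p] = M[r_p, t]; wildcard read symbols (-1) contribute the uniform
# marginal 1/4
.gvals <- function(r_int, Mmat, t_sym) {
  gv <- numeric(length(r_int))
  wc <- r_int < 0L
  gv[wc] <- 0.25
  gv[!wc] <- Mmat[r_int[!wc] + 1L, t_sym + 1L]
  gv
}

# index gv at positions pos, NA outside 1..L (observables may not reach
# outside the read)
.gidx <- function(gv, pos) {
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 1L & pos <= length(gv)
  out[ok] <- gv[pos[ok]]
  out
}

# one forward step: from F_i (vector over ys) to F_{i+1}, consuming label
# t_i at global step i
.fwd_step <- function(Fi, i, ys, r_int, Mmat, t_i, tab) {
  W <- length(Fi)
  sv <- .gidx(.gvals(r_int, Mmat, t_i), i + ys)
  Fn <- tab$q0 * c(Fi[-1L], 0)
  for (l in seq_len(tab$I + 1L)) {
    e <- tab$del_c[l] + tab$sub_c[l] * sv
    e[is.na(e)] <- 0
    shifted <- if (l == 1L) Fi else c(numeric(l - 1L), Fi[seq_len(W - l + 1L)])
    Fn <- Fn + shifted * e
  }
  Fn
}

# full scaled forward pass; labels over Z4, prior over ys for F_1
.fwd <- function(r_int, labels, Mmat, H, prior, ys) {
  tab <- .hmm_tables(H)
  N <- length(labels)
  W <- length(ys)
  Fm <- matrix(0, N + 1L, W)
  logsc <- numeric(N + 1L)
  s0 <- sum(prior)
  if (s0 <= 0) stop("forward prior has no mass")
  Fm[1L, ] <- prior / s0
  logsc[1L] <- log(s0)
  for (i in seq_len(N)) {
    Fn <- .fwd_step(Fm[i, ], i, ys, r_int, Mmat, labels[i], tab)
    s <- sum(Fn)
    if (s <= 0) {
      logsc[(i + 1L):(N + 1L)] <- -Inf
      break
    }
    Fm[i + 1L, ] <- Fn / s
    logsc[i + 1L] <- logsc[i] + log(s)
  }
  list(F = Fm, logsc = logsc)
}

# full scaled backward pass; priorB over ys for B_N (stored at row N+1)
.bwd <- function(r_int, labels, Mmat, H, priorB, ys) {
  tab <- .hmm_tables(H)
  N <- length(labels)
  W <- length(ys)
  Bm <- matrix(0, N + 1L, W)
  logsc <- numeric(N + 1L)
  s0 <- sum(priorB)
  if (s0 <= 0) stop("backward prior has no mass")
  Bm[N + 1L, ] <- priorB / s0
  logsc[N + 1L] <- log(s0)
  for (i in N:1L) {
    Bi <- Bm[i + 1L, ]
    gv <- .gvals(r_int, Mmat, labels[i])
    Bn <- tab$q0 * c(0, Bi[-W])
    for (l in seq_len(tab$I + 1L)) {
      e <- tab$del_c[l] + tab$sub_c[l] * .gidx(gv, i + ys + l - 1L)
      e[is.na(e)] <- 0
      shifted <- if (l == 1L) Bi else c(Bi[l:W], numeric(l - 1L))
      Bn <- Bn + shifted * e
    }
    s <- sum(Bn)
    if (s <= 0) {
      logsc[i:1L] <- -Inf
      break
    }
    Bm[i, ] <- Bn / s
    logsc[i] <- logsc[i + 1L] + log(s)
  }
  list(B = Bm, logsc = logsc)
}

#' Forward-backward pass over the drift lattice
#'
#' Runs the scaled forward and backward recursions of the synchronization
#' HMM for a read against a label sequence (a barcode for `Q^S`-type
#' emissions, or the watermark with the effective substitution matrix for
#' the boundary pass). Drift states `y` range over `-N .. |r|`; read
#' positions referenced outside the read contribute zero. Row `i+1` of the
#' stored matrices holds `F_{i+1}` and `B_i` (the quantities meeting at cut
#' point `i`), in a scaled representation: true values are
#' `F[i+1, ] * exp(logscF[i+1])` and `B[i+1, ] * exp(logscB[i+1])`.
#'
#' @param r read DNA string (IUPAC ambiguity codes are treated as
#'   uniform-emission wildcards).
#' @param labels integer label sequence over Z4, length `N`.
#' @param H an `hmm_params`.
#' @param M substitution matrix used in the emissions: `H$S` (default) for
#'   decoding against a barcode, or an effective matrix from
#'   [effective_substitution()] for the watermark/boundary pass.
#' @param priorF prior over start drifts (vector over `-N..|r|`); default
#'   uniform on `0 <= y <= |r|`.
#' @param priorB prior over end drifts; default 1 on `-N <= y <= |r| - N`.
#' @return object of class `drift_lattice`: list with `F`, `B`, `logscF`,
#'   `logscB`, `ys` (drift values of the columns), `N`, `L`, `loglik`
#'   (total log-likelihood at cut 0) and `loglik_by_cut` (per-cut values,
#'   constant up to numerical error).
#' @export
forward_backward <- function(r, labels, H, M = H$S, priorF = NULL, priorB = NULL) {
  stopifnot(inherits(H, "hmm_params"))
  if (!nzchar(r)) stop("empty read")
  r_int <- .dna_map_wild(r)
  L <- length(r_int)
  labels <- as.integer(labels)
  N <- length(labels)
  ys <- (-N):L
  if (is.null(priorF)) {
    priorF <- as.numeric(ys >= 0L) / (L + 1)
  }
  if (is.null(priorB)) {
    priorB <- as.numeric(ys >= -N & ys <= L - N)
  }
  stopifnot(length(priorF) == length(ys), length(priorB) == length(ys))
  fw <- .fwd(r_int, labels, M, H, priorF, ys)
  bw <- .bwd(r_int, labels, M, H, priorB, ys)
  cuts <- vapply(0:N, function(i) {
    v <- sum(fw$F[i + 1L, ] * bw$B[i + 1L, ])
    log(v) + fw$logsc[i + 1L] + bw$logsc[i + 1L]
  }, numeric(1))
  structure(list(F = fw$F, B = bw$B, logscF = fw$logsc, logscB = bw$logsc,
                 ys = ys, N = N, L = L, r_int = r_int,
                 loglik = cuts[1L], loglik_by_cut = cuts),
            class = "drift_lattice")
}

#' Watermark lattice of a read
#'
#' Boundary-pass forward-backward: the read against the watermark of a
#' barcode set, with the effective substitution matrix absorbing the inner
#' code, and the conservative uniform boundary priors.
#'
#' @param r read DNA string.
#' @param set a `barcode_set`.
#' @param H an `hmm_params`.
#' @return a `drift_lattice`.
#' @export
watermark_lattice <- function(r, set, H) {
  stopifnot(inherits(set, "barcode_set"))
  E <- effective_substitution(H$S, set$inner)
  forward_backward(r, set$watermark, H, M = E)
}

#' Estimate barcode boundaries from a watermark lattice
#'
#' The likeliest drift at cut `i` is `argmax_y F_{i+1}(y) B_i(y)`; the
#' estimated barcode occupies `[start, end)` (0-based half-open) with
#' `start = x_hat_0` and `end = N + x_hat_N`. Ties break towards the
#' smaller drift.
#'
#' @param lattice a `drift_lattice` from the watermark pass.
#' @return list with `start` and `end` (integers).
#' @export
estimate_boundaries <- function(lattice) {
  stopifnot(inherits(lattice, "drift_lattice"))
  post0 <- lattice$F[1L, ] * lattice$B[1L, ]
  postN <- lattice$F[lattice$N + 1L, ] * lattice$B[lattice$N + 1L, ]
  if (all(post0 == 0) || all(postN == 0)) stop("synchronization failed")
  list(start = lattice$ys[which.max(post0)],
       end = lattice$N + lattice$ys[which.max(postN)])
}

#' Symbol-wise posterior probabilities of the outer symbols
#'
#' For block `j` spanning watermark positions `u = (j-1) n2 + 1` to
#' `v = j n2`, the likelihood of inner word `s` is
#' `sum_{y,z} F_u(y) pi_u(y, z, s) B_v(z)`, where `pi` restarts the forward
#' metric inside the block with emissions `Q^S(l, ., w_i + s_i mod 4)`. By
#' linearity the sum over starting drifts is computed as a single truncated
#' forward pass initialized with the (window-pruned) row `F_u`. Normalizing
#' across the `q1` inner words (uniform symbol prior) gives the posterior
#' of the outer symbol `d_j`.
#'
#' @param lattice watermark `drift_lattice` of the read (see
#'   [watermark_lattice()]).
#' @param set a `barcode_set`.
#' @param H an `hmm_params`; `H$Delta` prunes drifts farther than `Delta`
#'   from the likeliest drift at the block start.
#' @return `n1 x q1` matrix of posteriors; rows sum to 1.
#' @export
symbol_posteriors <- function(lattice, set, H) {
  stopifnot(inherits(lattice, "drift_lattice"), inherits(set, "barcode_set"))
  inner <- set$inner
  w <- set$watermark
  n1 <- set$config$n1
  n2 <- set$config$n2
  q1 <- inner$q1
  tab <- .hmm_tables(H)
  ys <- lattice$ys
  post <- matrix(0, n1, q1)
  for (j in seq_len(n1)) {
    u <- (j - 1L) * n2 + 1L
    v <- j * n2
    f0 <- lattice$F[u, ]
    bu <- lattice$B[u, ]
    yhat <- ys[which.max(f0 * bu)]
    f0[abs(ys - yhat) > H$Delta] <- 0       # drift window around the block start
    Bv <- lattice$B[v + 1L, ]
    lik <- numeric(q1)
    for (sidx in seq_len(q1)) {
      labels_blk <- (w[u:v] + inner$words[sidx, ]) %% 4L
      f <- f0
      for (step in seq_len(n2)) {
        f <- .fwd_step(f, u + step - 1L, ys, lattice$r_int, H$S,
                       labels_blk[step], tab)
      }
      lik[sidx] <- sum(f * Bv)
    }
    tot <- sum(lik)
    if (tot <= 0) stop("block decoding failed: zero posterior mass in block ", j)
    post[j, ] <- lik / tot
  }
  post
}

#' Optimal (full maximum-likelihood) decoding
#'
#' Evaluates `Pr(r | H, b)` for every barcode in the set by a forward pass
#' and returns the maximizer. For embedded reads the start prior is uniform
#' (as in the boundary pass) and the terminal value sums over admissible
#' end drifts; for non-embedded reads (`t = b`) the prior is a point mass
#' at drift 0 and the terminal value is `F_{N+1}(|r| - N)`. Ties break
#' towards the smallest message index. Exhaustive over the set, hence
#' `q1^k1` forward passes in the worst case: the symbol-wise decoder in
#' [decode()] exists to avoid this cost.
#'
#' @param r read DNA string.
#' @param set a `barcode_set`.
#' @param H an `hmm_params`.
#' @param embedded is the barcode embedded in context (default TRUE)?
#' @return list with `index` (decoded message index), `barcode`, `loglik`,
#'   and `logliks` (per-candidate vector, in set order).
#' @export
optimal_decode <- function(r, set, H, embedded = TRUE) {
  stopifnot(inherits(set, "barcode_set"), inherits(H, "hmm_params"))
  if (length(set$barcodes) == 0L) stop("empty barcode set")
  if (!nzchar(r)) stop("empty read")
  r_int <- .dna_map_wild(r)
  L <- length(r_int)
  N <- set$config$N
  tab <- .hmm_tables(H)
  Tm <- vapply(set$barcodes, dna_map, integer(N), USE.NAMES = FALSE)  # N x M
  M_n <- ncol(Tm)
  if (embedded) {
    ys <- (-N):L
    prior <- as.numeric(ys >= 0L)
  } else {
    ys <- max(-N, -H$Delta):min(L, H$Delta + max(0L, L - N))
    prior <- as.numeric(ys == 0L)
  }
  W <- length(ys)
  Fm <- matrix(prior / sum(prior), W, M_n)
  logsc <- numeric(M_n)
  alive <- rep(TRUE, M_n)
  for (i in seq_len(N)) {
    pos <- i + ys
    ok <- pos >= 1L & pos <= L
    rs <- r_int[pos[ok]]
    # substitution values for all candidates at once: rows = valid drifts
    sv <- matrix(0.25, sum(ok), M_n)
    real <- rs >= 0L
    sv[real, ] <- H$S[rs[real] + 1L, Tm[i, ] + 1L, drop = FALSE]
    Fn <- tab$q0 * rbind(Fm[-1L, , drop = FALSE], 0)
    for (l in seq_len(tab$I + 1L)) {
      e <- matrix(0, W, M_n)
      e[ok, ] <- tab$del_c[l] + tab$sub_c[l] * sv
      shifted <- if (l == 1L) Fm else
        rbind(matrix(0, l - 1L, M_n), Fm[seq_len(W - l + 1L), , drop = FALSE])
      Fn <- Fn + shifted * e
    }
    cs <- colSums(Fn)
    dead <- alive & cs <= 0
    if (any(dead)) {
      Fn[, dead] <- 0
      logsc[dead] <- -Inf
      alive[dead] <- FALSE
    }
    live <- which(alive)
    if (length(live)) {
      Fn[, live] <- sweep(Fn[, live, drop = FALSE], 2L, cs[live], "/")
      logsc[live] <- logsc[live] + log(cs[live])
    }
    Fm <- Fn
  }
  if (embedded) {
    term <- ys >= -N & ys <= L - N
    logliks <- log(colSums(Fm[term, , drop = FALSE])) + logsc
  } else {
    yi <- match(L - N, ys)
    logliks <- if (is.na(yi)) rep(-Inf, M_n) else log(Fm[yi, ]) + logsc
  }
  best <- which.max(logliks)
  list(index = set$indices[best], barcode = set$barcodes[best],
       loglik = logliks[best], logliks = logliks)
}

#' Decode a single read
#'
#' The symbol-wise decoder (default) runs the watermark forward-backward
#' pass, estimates the barcode boundaries, computes symbol-wise posteriors
#' of the outer symbols and soft-ML-decodes the outer code, restricted to
#' the message indices present in the set. The optimal decoder maximizes
#' the full read likelihood over all barcodes of the set. Both report
#' boundary estimates and a log-likelihood.
#'
#' @param r read DNA string.
#' @param set a `barcode_set` (typically a `designed_code`).
#' @param H an `hmm_params`.
#' @param mode `"symbolwise"` (default) or `"optimal"`.
#' @return object of class `decode_result`: list with `mode`, `index`
#'   (decoded message index), `message`, `barcode`, `start`, `end` (0-based
#'   half-open in the read), `posteriors` (`n1 x q1`, symbol-wise mode
#'   only) and `loglik`.
#' @export
decode <- function(r, set, H, mode = c("symbolwise", "optimal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "barcode_set"))
  if (mode == "optimal") {
    od <- optimal_decode(r, set, H, embedded = TRUE)
    lat <- forward_backward(r, dna_map(od$barcode), H, M = H$S)
    bnd <- estimate_boundaries(lat)
    res <- list(mode = mode, index = od$index,
                message = .all_messages(set$config$q1, set$config$k1)[od$index + 1L, ],
                barcode = od$barcode, start = bnd$start, end = bnd$end,
                posteriors = NULL, loglik = od$loglik)
  } else {
    lat <- watermark_lattice(r, set, H)
    bnd <- estimate_boundaries(lat)
    post <- symbol_posteriors(lat, set, H)
    ml <- ml_soft_decode_restricted(set$outer, post, set$indices)
    res <- list(mode = mode, index = ml$index, message = ml$message,
                barcode = assemble_barcode(ml$message, set$outer, set$inner,
                                           set$watermark),
                start = bnd$start, end = bnd$end,
                posteriors = post, loglik = ml$score)
  }
  structure(res, class = "decode_result")
}

#' Soft ML decoding restricted to a subset of messages
#'
#' As [ml_soft_decode()], but the argmax runs only over the given message
#' indices (the survivors of the constraint filter); used by demultiplexing
#' so that reads are only ever assigned to barcodes that exist in the set.
#'
#' @inheritParams ml_soft_decode
#' @param indices 0-based message indices to consider.
#' @export
ml_soft_decode_restricted <- function(code, posteriors, indices) {
  stopifnot(inherits(code, "outer_code"))
  if (any(posteriors < 0)) stop("negative posterior")
  if (any(rowSums(posteriors) == 0)) stop("degenerate posteriors: all-zero row")
  lp <- log(posteriors)
  cb <- code$codebook[indices + 1L, , drop = FALSE]
  m <- nrow(cb)
  idx <- cbind(rep(seq_len(code$n1), each = m), as.vector(cb) + 1L)
  scores <- rowSums(matrix(lp[idx], m, code$n1))
  best <- which.max(scores)
  list(message = .all_messages(code$field$q, code$k1)[indices[best] + 1L, ],
       index = indices[best], codeword = cb[best, ], score = scores[best])
}

#' Demultiplex a batch of reads
#'
#' Decodes each read and collects assignments; reads on which
#' synchronization or block decoding fails are flagged unassigned (`NA`
#' index) rather than raising an error.
#'
#' @param reads named character vector of read sequences.
#' @param set a `barcode_set`.
#' @param H an `hmm_params`.
#' @param mode decoder mode, see [decode()].
#' @return data.frame with columns `read_id`, `index` (NA if unassigned),
#'   `loglik`, `start`, `end`, `mode`.
#' @export
demux_reads <- function(reads, set, H, mode = c("symbolwise", "optimal")) {
  mode <- match.arg(mode)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    res <- tryCatch(decode(reads[[i]], set, H, mode), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(read_id = ids[i], index = NA_integer_, loglik = NA_real_,
                 start = NA_integer_, end = NA_integer_, mode = mode)
    } else {
      data.frame(read_id = ids[i], index = res$index, loglik = res$loglik,
                 start = res$start, end = res$end, mode = mode)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.decode_result <- function(x, ...) {
  cat("Decoded (", x$mode, "): index ", x$index, ", barcode ", x$barcode,
      ", span [", x$start, ", ", x$end, "), loglik ",
      format(x$loglik, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("HMM parameters: p_i = ", x$p_i, ", p_d = ", x$p_d, ", I = ", x$I,
      ", Delta = ", x$Delta, "\n", sep = "")
  invisible(x)
}
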