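# Linear-chain CRF layer: log-likelihood, marginals and Viterbi decoding
# over an emission score matrix. Shared by the feature-based CRF tagger and
# the BiLSTM-CRF output layer.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix
col_logsumexp <- function(A) {
  m <- apply(A, 2, max)
  finite <- is.finite(m)
  out <- m
  if (any(finite)) {
    out[finite] <- m[finite] +
      log(colSums(exp(sweep(A[, finite, drop = FALSE], 2, m[finite]))))
  }
  out
}

# Negative log-likelihood of gold path `y` (integer label ids) under
# emissions E (T x L), transition matrix trans (L x L, from row to column)
# and start scores, plus gradients w.r.t. all three.
crf_layer_grad <- function(E, trans, start, y) {
  T_ <- nrow(E)
  L <- ncol(E)
  # forward
  alpha <- matrix(0, T_, L)
  alpha[1, ] <- start + E[1, ]
  if (T_ > 1) {
    for (t in 2:T_) {
      alpha[t, ] <- E[t, ] + col_logsumexp(alpha[t - 1, ] + trans)
    }
  }
  logZ <- logsumexp(alpha[T_, ])
  # backward
  beta <- matrix(0, T_, L)
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      beta[t, ] <- col_logsumexp(t(trans) + (E[t + 1, ] + beta[t + 1, ]))
    }
  }
  # marginals
  P <- exp(alpha + beta - logZ)           # T x L unary marginals
  dE <- P
  dstart <- P[1, ]
  dtrans <- matrix(0, L, L)
  if (T_ > 1) {
    for (t in 2:T_) {
      M <- outer(alpha[t - 1, ], E[t, ] + beta[t, ], `+`) + trans - logZ
      dtrans <- dtrans + exp(M)
    }
  }
  # subtract empirical counts
  gold_score <- start[y[1]] + sum(E[cbind(seq_len(T_), y)])
  dE[cbind(seq_len(T_), y)] <- dE[cbind(seq_len(T_), y)] - 1
  dstart[y[1]] <- dstart[y[1]] - 1
  if (T_ > 1) {
    for (t in 2:T_) {
      gold_score <- gold_score + trans[y[t - 1], y[t]]
      dtrans[y[t - 1], y[t]] <- dtrans[y[t - 1], y[t]] - 1
    }
  }
  list(nll = logZ - gold_score, dE = dE, dtrans = dtrans, dstart = dstart)
}

# IOB2 structural constraints over the label alphabet: I-tau may only follow
# B-tau or I-tau, and no sequence may start with I-tau.
iob2_constraints <- function(labels = iob2_labels()) {
  L <- length(labels)
  is_i <- startsWith(labels, "I-")
  tau <- sub("^[BI]-", "", labels)
  trans_ok <- matrix(TRUE, L, L)
  for (j in which(is_i)) {
    trans_ok[, j] <- startsWith(labels, "B-") | startsWith(labels, "I-")
    trans_ok[tau != tau[j], j] <- FALSE
  }
  start_ok <- !is_i
  list(trans_ok = trans_ok, start_ok = start_ok)
}

# Viterbi decoding with optional structural constraints (invalid moves get
# -Inf), guaranteeing IOB2-valid output.
crf_viterbi <- function(E, trans, start, constraints = iob2_constraints()) {
  T_ <- nrow(E)
  L <- ncol(E)
  if (T_ == 0) return(integer(0))
  trans_c <- trans
  start_c <- start
  if (!is.null(constraints)) {
    trans_c[!constraints$trans_ok] <- -Inf
    start_c[!constraints$start_ok] <- -Inf
  }
  delta <- matrix(-Inf, T_, L)
  psi <- matrix(0L, T_, L)
  delta[1, ] <- start_c + E[1, ]
  if (T_ > 1) {
    for (t in 2:T_) {
      M <- delta[t - 1, ] + trans_c            # L x L: from row, to column
      psi[t, ] <- max.col(t(M), ties.method = "first")
      delta[t, ] <- M[cbind(psi[t, ], seq_len(L))] + E[t, ]
    }
  }
  y <- integer(T_)
  y[T_] <- which.max(delta[T_, ])
  if (T_ > 1) {
    for (t in (T_ - 1):1) y[t] <- psi[t + 1, y[t + 1]]
  }
  y
}
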