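# Independent explicit-loop oracles and shared fixtures. The oracles
# deliberately avoid the package's vectorized code paths: everything is
# written as scalar loops so agreement is evidence, not tautology.

EPS_CLAMP <- 1e-7

oracle_cross_entropy <- function(y, p) {
  y <- as.matrix(y); p <- as.matrix(p)
  total <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    pij <- min(max(p[i, j], EPS_CLAMP), 1 - EPS_CLAMP)
    total <- total - y[i, j] * log(pij)
  }
  total / nrow(y)
}

oracle_kl <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  pc <- pmin(pmax(p, EPS_CLAMP), 1 - EPS_CLAMP)
  qc <- pmin(pmax(q, EPS_CLAMP), 1 - EPS_CLAMP)
  total <- 0
  for (i in seq_len(nrow(p))) {
    pr <- pc[i, ] / sum(pc[i, ])
    qr <- qc[i, ] / sum(qc[i, ])
    for (j in seq_len(ncol(p)))
      total <- total + pr[j] * log(pr[j] / qr[j])
  }
  total / nrow(p)
}

oracle_feature_l2 <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  total <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    total <- total + (A[i, j] - B[i, j])^2
  total / length(A)
}

# gate-by-gate scalar LSTM step (standard equations, tanh cell squashing)
oracle_lstm_step <- function(par, x, h_prev, c_prev,
                             cell_activation = "tanh") {
  H <- length(h_prev)
  sig <- function(z) 1 / (1 + exp(-z))
  f <- i <- o <- g <- numeric(H)
  for (u in seq_len(H)) {
    f[u] <- sig(sum(par$W_f[u, ] * x) + sum(par$U_f[u, ] * h_prev) + par$b_f[u])
    i[u] <- sig(sum(par$W_i[u, ] * x) + sum(par$U_i[u, ] * h_prev) + par$b_i[u])
    o[u] <- sig(sum(par$W_o[u, ] * x) + sum(par$U_o[u, ] * h_prev) + par$b_o[u])
    g[u] <- tanh(sum(par$W_c[u, ] * x) + sum(par$U_c[u, ] * h_prev) + par$b_c[u])
  }
  cn <- f * c_prev + i * g
  sq <- if (cell_activation == "tanh") tanh(cn) else sig(cn)
  list(h = o * sq, c = cn)
}

# explicit double-loop 1-D multi-channel convolution
oracle_conv <- function(w, b, x_mat, stride) {
  # w: out x in x k ; x_mat: in_channels x length
  d <- dim(w); n_out <- d[1]; n_in <- d[2]; k <- d[3]
  L <- ncol(x_mat)
  L_out <- floor((L - k) / stride) + 1
  out <- matrix(0, n_out, L_out)
  for (e in seq_len(n_out)) for (pos in seq_len(L_out)) {
    s <- 0
    for (ci in seq_len(n_in)) for (kk in seq_len(k))
      s <- s + w[e, ci, kk] * x_mat[ci, (pos - 1) * stride + kk]
    out[e, pos] <- s + b[e]
  }
  out
}

oracle_f1 <- function(tp, fp, fn) {
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

# Table 1 worked example: the subject observed at weeks 0 and 52 only, on
# canonical grid (0, 4, 12, 52); four named features as printed
table1_features <- c("Ruminococcaceae", "Peptostreptococcaceae",
                     "Alcaligenaceae", "Porphyromonadaceae")
table1_week0 <- c(0.29747, 0.00381, 0.00114, 0.18839)
table1_week52 <- c(0.00168, 0.00839, 0.00839, 0.50269)

table1_cohort <- function() {
  vals <- rbind(table1_week0, table1_week52)
  tab <- suppressWarnings(
    abundance_table(vals, c("subj1_w0", "subj1_w52"), table1_features))
  meta <- sample_metadata(data.frame(
    sample_id = c("subj1_w0", "subj1_w52"),
    subject_id = "subj1", time_point = c(0, 52), label = "case",
    stringsAsFactors = FALSE))
  assemble_cohort(tab, meta, canonical_grid = c(0, 4, 12, 52))
}

# small, fast network configuration for training-path tests
tiny_net <- function(...) {
  net_config(hidden_size = 8, head_hidden = 8, epochs = 5, batch_size = 16,
             conv_layers = list(list(out_channels = 4, kernel_size = 5,
                                     stride = 2)),
             ...)
}

small_cohort <- function(n = 30, Fk = 12, seed = 42, ...) {
  syn <- generate(synth_config(n_subjects = n, n_features = Fk, seed = seed,
                               ...))
  assemble_cohort(syn$table, syn$meta, syn$canonical_grid)
}
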