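# Feed-forward stacks and the gated recurrent unit, expressed both as
# weight initializers (plain nested lists of matrices) and as tape
# builders. All activations are SELU; weights follow the
# self-normalizing convention W ~ N(0, 1/fan_in), biases start at zero.

#' Initialize feed-forward network weights
#'
#' A stack of linear layers with SELU activations between them and a
#' linear output. `hidden` may be empty, giving a single linear map.
#'
#' @param d_in,d_out input and output widths.
#' @param hidden integer vector of hidden layer widths (possibly empty).
#' @return a list with matrices `W` and bias rows `b`, one per layer.
#' @export
ffnn_weights <- function(d_in, hidden, d_out) {
  widths <- c(d_in, hidden, d_out)
  W <- list()
  b <- list()
  for (i in seq_len(length(widths) - 1L)) {
    W[[i]] <- matrix(stats::rnorm(widths[i] * widths[i + 1L], sd = sqrt(1 / widths[i])),
                     widths[i], widths[i + 1L])
    b[[i]] <- matrix(0, 1L, widths[i + 1L])
  }
  list(W = W, b = b)
}

#' Initialize gated recurrent unit weights
#'
#' @param d_in input width, `d_hidden` state width.
#' @param d_hidden hidden state width.
#' @return named list of gate matrices (`Wz`, `Uz`, `bz`, `Wr`, `Ur`,
#'   `br`, `Wn`, `Un`, `bn`).
#' @export
gru_weights <- function(d_in, d_hidden) {
  mk <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(1 / a)), a, b)
  list(Wz = mk(d_in, d_hidden), Uz = mk(d_hidden, d_hidden), bz = matrix(0, 1, d_hidden),
       Wr = mk(d_in, d_hidden), Ur = mk(d_hidden, d_hidden), br = matrix(0, 1, d_hidden),
       Wn = mk(d_in, d_hidden), Un = mk(d_hidden, d_hidden), bn = matrix(0, 1, d_hidden))
}

# tape builder: x node -> output node; SELU between layers, linear last
ffnn_fwd <- function(tape, pn, x) {
  nl <- length(pn$W)
  for (i in seq_len(nl)) {
    x <- ad_add_bias(tape, ad_mm(tape, x, pn$W[[i]]), pn$b[[i]])
    if (i < nl) x <- ad_selu(tape, x)
  }
  x
}

# GRU cell: message as input, current state as hidden.
#   z = sigma(x Wz + h Uz + bz)          update gate
#   r = sigma(x Wr + h Ur + br)          reset gate
#   n = tanh(x Wn + r (h Un) + bn)       candidate
#   h' = (1 - z) n + z h
gru_fwd <- function(tape, pn, x, h) {
  lin <- function(W, U, b) {
    ad_add_bias(tape, ad_add(tape, ad_mm(tape, x, W), ad_mm(tape, h, U)), b)
  }
  z <- ad_sigmoid(tape, lin(pn$Wz, pn$Uz, pn$bz))
  r <- ad_sigmoid(tape, lin(pn$Wr, pn$Ur, pn$br))
  n <- ad_tanh(tape, ad_add_bias(
    tape,
    ad_add(tape, ad_mm(tape, x, pn$Wn), ad_mul(tape, r, ad_mm(tape, h, pn$Un))),
    pn$bn))
  one <- ad_const(tape, matrix(1, nrow(z$val), ncol(z$val)))
  ad_add(tape, ad_mul(tape, ad_sub(tape, one, z), n), ad_mul(tape, z, h))
}
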