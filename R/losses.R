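# The three training losses: asymmetric confidence-weighted multi-label
# classification, contrastive knowledge-embedding, and protein-ID aggregation,
# plus their weighted combination. Gradients are returned by internal *_grad
# helpers so the trainer can backpropagate without an autodiff framework.

.eps_log <- 1e-12

#' The nine low-variability localization classes used by the ID-aggregation loss
#' @export
pida_default_classes <- c(
  "cytoplasm", "nucleoplasm", "nucleolus", "focal_adhesions",
  "cell_contact", "membrane", "er", "vesicles", "golgi"
)

#' Loss configuration
#'
#' Collects the tunable parameters of the three losses: the asymmetric
#' focusing exponent `r` and probability margin `m` of the classification
#' loss, the per-grade confidence weights `alpha_by_grade` (grade 3 =
#' prominent signal, 1 = subtle), the ID-loss analogues `r_id`/`m_id`, the
#' class set on which the ID-aggregation loss is active, and the mixing
#' weights of the combined objective.
#'
#' @param r Focusing exponent for negative classes (default 4).
#' @param m Probability margin subtracted from negative-class probabilities
#'   before focusing (default 0.05).
#' @param alpha_by_grade Named numeric vector mapping confidence grades
#'   `"1"`, `"2"`, `"3"` to positive-class weights.
#' @param r_id,m_id Focusing exponent and margin of the protein-ID loss.
#' @param pida_classes Character vector of localization classes that activate
#'   the ID-aggregation loss for a cell.
#' @param w_slc,w_ke,w_id Weights of the classification, knowledge-embedding
#'   and ID losses in the total objective.
#' @return A list of class `subloc3d_loss_config`.
#' @export
loss_config <- function(r = 4, m = 0.05,
                        alpha_by_grade = c(`3` = 1.0, `2` = 0.5, `1` = 0.1),
                        r_id = 4, m_id = 0.1,
                        pida_classes = pida_default_classes,
                        w_slc = 1.0, w_ke = 0.1, w_id = 0.1) {
  stopifnot(r >= 0, r_id >= 0, m >= 0, m < 1, m_id >= 0, m_id < 1,
            all(alpha_by_grade > 0), w_slc >= 0, w_ke >= 0, w_id >= 0)
  structure(
    list(r = r, m = m, alpha_by_grade = alpha_by_grade, r_id = r_id,
         m_id = m_id, pida_classes = pida_classes,
         weights = c(w_slc = w_slc, w_ke = w_ke, w_id = w_id)),
    class = "subloc3d_loss_config"
  )
}

#' Per-class confidence weights from grades
#'
#' Positive classes take the weight of their confidence grade; negative
#' classes take weight 1 (grades only annotate positive labels).
#'
#' @param y_true 0/1 vector or C x B matrix of labels.
#' @param grades Integer vector/matrix of the same shape; entries only read
#'   where `y_true == 1`.
#' @param config A [loss_config()].
#' @return Numeric weights, same shape as `y_true`.
#' @export
alpha_from_grades <- function(y_true, grades, config = loss_config()) {
  alpha <- y_true * 0 + 1
  pos <- which(y_true == 1)
  if (length(pos)) {
    g <- grades[pos]
    if (any(!g %in% c(1L, 2L, 3L))) stop("confidence grades must be in {1,2,3}")
    alpha[pos] <- config$alpha_by_grade[as.character(g)]
  }
  alpha
}

#' Asymmetric confidence-weighted classification loss
#'
#' For class j with predicted probability p and label y:
#' `L_j = alpha_j * (-y log p - (1-y) (p-)^r log(1 - p-))` with
#' `p- = max(p - m, 0)`; the loss is the mean over the C classes, and for a
#' matrix input additionally the mean over batch columns. Logs are clamped at
#' 1e-12 so the loss is finite on the closed unit interval.
#'
#' @param y_prob Probabilities in `[0,1]`, vector of length C or C x B matrix.
#' @param y_true 0/1 labels, same shape.
#' @param alpha Per-class weights (same shape); defaults to 1 everywhere.
#' @param config A [loss_config()].
#' @return Non-negative scalar.
#' @export
slc_loss <- function(y_prob, y_true, alpha = NULL, config = loss_config()) {
  if (anyNA(y_prob) || anyNA(y_true)) stop("NaN/NA in slc_loss inputs")
  stopifnot(length(y_prob) == length(y_true))
  if (is.null(alpha)) alpha <- y_prob * 0 + 1
  p <- pmin(pmax(y_prob, .eps_log), 1 - .eps_log)
  pm <- pmax(y_prob - config$m, 0)
  neg_log <- log(pmax(1 - pm, .eps_log))
  term <- -y_true * log(p) - (1 - y_true) * pm^config$r * neg_log
  per_class <- alpha * term
  C <- if (is.matrix(y_prob)) nrow(y_prob) else length(y_prob)
  B <- length(y_prob) / C
  sum(per_class) / (C * B)
}

#' @noRd
slc_loss_grad <- function(y_prob, y_true, alpha = NULL, config = loss_config()) {
  if (is.null(alpha)) alpha <- y_prob * 0 + 1
  C <- if (is.matrix(y_prob)) nrow(y_prob) else length(y_prob)
  B <- length(y_prob) / C
  p <- pmin(pmax(y_prob, .eps_log), 1 - .eps_log)
  pm <- pmax(y_prob - config$m, 0)
  r <- config$r
  one_m <- pmax(1 - pm, .eps_log)
  dpos <- -y_true / p
  # d/dp [ -(p-)^r log(1-p-) ] for p > m, 0 otherwise
  active <- y_prob > config$m
  dneg <- ifelse(active,
                 -(r * pm^pmax(r - 1, 0) * log(one_m) - pm^r / one_m),
                 0)
  alpha * (dpos + (1 - y_true) * dneg) / (C * B)
}

#' Contrastive knowledge-embedding loss for one triple
#'
#' `-log sigma(gamma - d_pos) - mean_i log sigma(d_neg_i - gamma)`, where
#' `d_pos` is the score of the true triple and `d_neg` the scores of
#' category-aware corrupted triples; lower scores mean more plausible.
#'
#' @param d_pos Scalar score of the positive triple.
#' @param d_negs Numeric vector of negative-triple scores (length >= 1).
#' @param gamma Margin hyperparameter (the maximal plausible score).
#' @return Non-negative scalar.
#' @export
ke_loss <- function(d_pos, d_negs, gamma) {
  if (length(d_negs) < 1) stop("ke_loss needs at least one negative score")
  # -log(sigmoid(x)) = log1p(exp(-x)), numerically stable
  nll <- function(x) ifelse(x > 0, log1p(exp(-x)), -x + log1p(exp(x)))
  nll(gamma - d_pos) + mean(nll(d_negs - gamma))
}

#' @noRd
ke_loss_grad <- function(d_pos, d_negs, gamma) {
  list(d_pos = 1 - sigmoid(gamma - d_pos),
       d_negs = -(1 - sigmoid(d_negs - gamma)) / length(d_negs))
}

#' Protein-ID aggregation loss
#'
#' Asymmetric single-label loss over the N training proteins, active only
#' when the cell carries at least one localization class from
#' `config$pida_classes`; otherwise returns 0.
#'
#' @param id_probs Probability simplex vector of length N (or N x B matrix
#'   with `true_id`/`sample_labels` as vectors/lists per column).
#' @param true_id Integer in `[0, N)`: index of the cell's protein.
#' @param sample_labels Character vector of the cell's localization classes.
#' @param config A [loss_config()].
#' @return Non-negative scalar.
#' @export
pida_loss <- function(id_probs, true_id, sample_labels, config = loss_config()) {
  N <- length(id_probs)
  if (true_id < 0 || true_id >= N) stop("true_id must be in [0, N)")
  if (!length(intersect(sample_labels, config$pida_classes))) return(0)
  y <- numeric(N)
  y[true_id + 1L] <- 1
  p <- pmin(pmax(id_probs, .eps_log), 1 - .eps_log)
  pm <- pmax(id_probs - config$m_id, 0)
  neg_log <- log(pmax(1 - pm, .eps_log))
  sum(-y * log(p) - (1 - y) * pm^config$r_id * neg_log) / N
}

#' @noRd
pida_loss_grad <- function(id_probs, true_id, sample_labels,
                           config = loss_config()) {
  N <- length(id_probs)
  if (!length(intersect(sample_labels, config$pida_classes))) return(numeric(N))
  y <- numeric(N)
  y[true_id + 1L] <- 1
  p <- pmin(pmax(id_probs, .eps_log), 1 - .eps_log)
  pm <- pmax(id_probs - config$m_id, 0)
  r <- config$r_id
  one_m <- pmax(1 - pm, .eps_log)
  active <- id_probs > config$m_id
  dneg <- ifelse(active,
                 -(r * pm^pmax(r - 1, 0) * log(one_m) - pm^r / one_m),
                 0)
  (-y / p + (1 - y) * dneg) / N
}

#' Weighted total loss
#'
#' @param l_slc,l_ke,l_id Component losses.
#' @param weights Named vector `c(w_slc=, w_ke=, w_id=)`; defaults to the
#'   1 / 0.1 / 0.1 mixture.
#' @return Scalar.
#' @export
total_loss <- function(l_slc, l_ke, l_id,
                       weights = c(w_slc = 1.0, w_ke = 0.1, w_id = 0.1)) {
  stopifnot(is.finite(l_slc), is.finite(l_ke), is.finite(l_id))
  unname(weights["w_slc"] * l_slc + weights["w_ke"] * l_ke +
           weights["w_id"] * l_id)
}
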