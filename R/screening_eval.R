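# Virtual-screening enrichment: ROC construction, AUC, rule-of-five.

#' ROC curve of a scored active/decoy table
#'
#' Ligands are ranked best-first (lower score = stronger predicted binding
#' by default, the docking-energy convention). One vertex is emitted per
#' distinct score value, so tied scores advance the true- and
#' false-positive rates jointly; the curve runs from (0,0) to (1,1).
#'
#' @param scores a `score_table` (columns `ligand_id`, `score`, `label`).
#' @param higher_better rank higher scores as better instead.
#' @return data.frame of class `roc_curve` with columns `fpr`, `tpr`, `tp`,
#'   `fp`, `tn`, `fn` and attributes `n_active`, `n_decoy`.
#' @export
roc_points <- function(scores, higher_better = FALSE) {
  if (!all(c("score", "label") %in% names(scores)))
    stop("score table needs 'score' and 'label' columns")
  n_act <- sum(scores$label == "active")
  n_dec <- sum(scores$label == "decoy")
  if (n_act == 0L || n_dec == 0L)
    stop("ROC needs at least one active and one decoy")
  s <- if (higher_better) -scores$score else scores$score
  ord <- order(s)
  is_act <- scores$label[ord] == "active"
  s <- s[ord]
  # last index of each distinct score = a joint threshold step
  step <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(is_act)[step]
  fp <- cumsum(!is_act)[step]
  df <- data.frame(fpr = c(0, fp / n_dec), tpr = c(0, tp / n_act),
                   tp = c(0L, tp), fp = c(0L, fp),
                   tn = n_dec - c(0L, fp), fn = n_act - c(0L, tp))
  attr(df, "n_active") <- n_act
  attr(df, "n_decoy") <- n_dec
  class(df) <- c("roc_curve", "data.frame")
  df
}

#' Area under a ROC curve
#'
#' Trapezoidal integration of the curve; with the joint-step handling of
#' ties this equals the Mann-Whitney probability of correctly ranking a
#' random active/decoy pair, ties credited one half.
#'
#' @param x a [roc_points()] curve, or a `score_table` (the curve is built
#'   first).
#' @param ... passed to [roc_points()] when `x` is a score table.
#' @return AUC in [0, 1].
#' @export
auc <- function(x, ...) {
  if (!inherits(x, "roc_curve")) x <- roc_points(x, ...)
  sum(diff(x$fpr) * (x$tpr[-1L] + x$tpr[-nrow(x)]) / 2)
}

#' Lipinski rule-of-five check
#'
#' Criteria, all inclusive: molecular weight <= 500 g/mol, logP <= 5,
#' hydrogen-bond acceptors (N or O) <= 10, hydrogen-bond donors (NH or OH)
#' <= 5. The strict variant fails on any violation (default); the classic
#' variant tolerates one.
#'
#' @param mw molecular weight (g/mol), or a list/data.frame row with fields
#'   `mw`, `logp`, `hba`, `hbd`.
#' @param logp octanol-water partition coefficient.
#' @param hba hydrogen-bond acceptor count.
#' @param hbd hydrogen-bond donor count.
#' @param allow_one tolerate a single violation?
#' @return list with `pass` (logical) and `violations` (character vector
#'   among `"MW"`, `"logP"`, `"HBA"`, `"HBD"`).
#' @export
rule_of_five <- function(mw, logp = NULL, hba = NULL, hbd = NULL,
                         allow_one = FALSE) {
  if (is.list(mw)) {
    d <- mw
    for (f in c("mw", "logp", "hba", "hbd"))
      if (is.null(d[[f]])) stop("missing descriptor field: ", f)
    mw <- d$mw; logp <- d$logp; hba <- d$hba; hbd <- d$hbd
  }
  if (is.null(logp) || is.null(hba) || is.null(hbd))
    stop("rule_of_five needs mw, logp, hba and hbd")
  if (mw <= 0) stop("molecular weight must be positive")
  if (hba < 0 || hbd < 0 || hba != round(hba) || hbd != round(hbd))
    stop("H-bond donor/acceptor counts must be non-negative integers")
  violations <- c("MW", "logP", "HBA", "HBD")[
    c(mw > 500, logp > 5, hba > 10, hbd > 5)]
  list(pass = length(violations) <= if (allow_one) 1L else 0L,
       violations = violations)
}

#' Rule-of-five verdicts for a descriptor table
#'
#' @param descriptors data.frame with columns `mw`, `logp`, `hba`, `hbd`
#'   (and optionally an id column, preserved).
#' @param allow_one tolerate one violation per molecule?
#' @return the input with `pass` and `violations` columns appended.
#' @export
rule_of_five_table <- function(descriptors, allow_one = FALSE) {
  need <- c("mw", "logp", "hba", "hbd")
  missing <- setdiff(need, names(descriptors))
  if (length(missing) > 0L)
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "))
  verdicts <- lapply(seq_len(nrow(descriptors)), function(i)
    rule_of_five(descriptors$mw[i], descriptors$logp[i],
                 descriptors$hba[i], descriptors$hbd[i],
                 allow_one = allow_one))
  descriptors$pass <- vapply(verdicts, `[[`, TRUE, "pass")
  descriptors$violations <- vapply(verdicts, function(v)
    paste(v$violations, collapse = ";"), "")
  descriptors
}
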