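# residues owning each restraint: identity of the copy-1 atoms
owning_residues <- function(rl, s) {
  r <- rl$restraints
  rk <- residue_key(s$atoms)
  list(res_i = rk[r$i1], res_j = rk[r$j1])
}

#' Plateau ratio of each restrained residue
#'
#' For every residue touched by at least one restraint (through either
#' copy-1 atom), the ratio of its actual summed penalty to the maximum
#' possible (all touching restraints in the plateau):
#' \eqn{\rho = \sum V(\Delta) / (V_{max} N)}. A ratio near 1 means the
#' residue's environment is genuinely distinct between the copies; near 0
#' means the copies agree.
#'
#' Ratios use the unweighted penalty, so they are independent of the list
#' weight.
#'
#' @param lists a `restraint_list` or list of them (evaluated at current
#'   coordinates internally).
#' @param s the structure.
#' @param target fixed target structure for target-kind lists.
#' @return data frame: `chain`, `resnum`, `icode`, `n_restraints`, `ratio`.
#' @export
plateau_ratios <- function(lists, s, target = NULL) {
  if (inherits(lists, "restraint_list")) lists <- list(lists)
  lists <- lapply(lists, evaluate_restraints, s = s, target = target)
  acc_v <- numeric(); acc_n <- numeric(); acc_vmax <- numeric()
  env <- new.env(parent = emptyenv())
  tally <- list()
  for (rl in lists) {
    if (!nrow(rl$restraints)) next
    own <- owning_residues(rl, s)
    for (side in own) {
      df <- data.frame(res = side, v = rl$restraints$v,
                       vmax = rl$params$v_max, stringsAsFactors = FALSE)
      tally[[length(tally) + 1L]] <- df
    }
    # a restraint fully inside one residue must count once, not twice
    both <- own$res_i == own$res_j
    if (any(both)) {
      tally[[length(tally)]] <- tally[[length(tally)]][!both, , drop = FALSE]
    }
  }
  if (!length(tally)) {
    return(data.frame(chain = character(), resnum = integer(),
                      icode = character(), n_restraints = integer(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  }
  all_t <- do.call(rbind, tally)
  agg_v <- tapply(all_t$v, all_t$res, sum)
  agg_n <- tapply(all_t$v, all_t$res, length)
  agg_m <- tapply(all_t$vmax, all_t$res, max)
  res <- names(agg_v)
  parts <- strsplit(res, "|", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, "", 1),
    resnum = as.integer(vapply(parts, `[`, "", 2)),
    icode = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    n_restraints = as.integer(agg_n),
    ratio = as.numeric(agg_v) / (agg_m * agg_n),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chain, out$resnum, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plateau ratio of a single residue
#'
#' @param lists,s,target as in [plateau_ratios()].
#' @param chain,resnum,icode residue identity (copy-1 side).
#' @return the ratio in `[0, 1]`, or `NA` when the residue participates in
#'   no restraint (not applicable).
#' @export
plateau_ratio <- function(lists, s, chain, resnum, icode = "", target = NULL) {
  pr <- plateau_ratios(lists, s, target)
  hit <- pr$chain == chain & pr$resnum == resnum & pr$icode == icode
  if (!any(hit)) return(NA_real_)
  pr$ratio[hit]
}

#' Prune restraints for residues with genuinely distinct conformations
#'
#' Stage 1 (plateau-ratio rule): a residue whose [plateau_ratios()] value
#' exceeds `ratio_threshold` (strictly) has distinct environments in the
#' NCS copies; every restraint touching it is removed. Stage 2 (gradient
#' rule, optional): among surviving residues, those whose mean per-atom
#' gradient magnitude exceeds `gradient_k` times the structure-wide median
#' are removed as "distinct but similar" — large gradients indicate the
#' restraints are fighting the data. The paper-style workflow enables both
#' (`-autoncs`); `gradient_k = NA` disables stage 2 (`-autoncs_noprune`
#' disables both — simply do not call `prune_restraints`).
#'
#' Pruning is a per-invocation action evaluated at the current coordinates;
#' lists are not re-pruned during minimisation.
#'
#' @param lists a `restraint_list` or list of them.
#' @param s the structure.
#' @param ratio_threshold plateau-ratio threshold, default 0.5.
#' @param gradient_k relative gradient threshold (multiple of the median),
#'   default `NA` (off); the field gives no absolute scale, so a relative
#'   rule with default 5 is used when enabled.
#' @param target fixed target structure for target-kind lists.
#' @return list with `lists` (pruned, same classes) and `report` (a
#'   `prune_report` data frame: residue identity, `n_restraints`, `ratio`,
#'   `mean_grad`, `decision`), plus `removed` counts as an attribute.
#' @export
prune_restraints <- function(lists, s, ratio_threshold = 0.5, gradient_k = NA,
                             target = NULL) {
  single <- inherits(lists, "restraint_list")
  if (single) lists <- list(lists)
  lists <- lapply(lists, evaluate_restraints, s = s, target = target)
  pr <- plateau_ratios(lists, s, target)
  if (!nrow(pr)) {
    rep0 <- pr; rep0$mean_grad <- numeric(0); rep0$decision <- character(0)
    class(rep0) <- c("prune_report", class(rep0))
    return(list(lists = if (single) lists[[1]] else lists, report = rep0))
  }
  res_id <- paste(pr$chain, pr$resnum, pr$icode, sep = "|")
  decision <- rep("kept", nrow(pr))
  decision[pr$ratio > ratio_threshold] <- "pruned_ratio"
  lists1 <- drop_residues(lists, s, res_id[decision == "pruned_ratio"])
  mean_grad <- rep(NA_real_, nrow(pr))
  if (!is.na(gradient_k)) {
    G <- lssr_gradient(lists1, s, target)
    gmag <- sqrt(rowSums(G^2))
    rk <- residue_key(s$atoms)
    surv <- which(decision == "kept")
    for (k in surv) {
      rows <- which(rk == res_id[k])
      mean_grad[k] <- mean(gmag[rows])
    }
    med <- stats::median(mean_grad[surv], na.rm = TRUE)
    # degenerate flat case (all gradients ~ 0): nothing to prune
    if (is.finite(med) && med > 1e-12) {
      decision[!is.na(mean_grad) & decision == "kept" &
                 mean_grad > gradient_k * med] <- "pruned_gradient"
      lists1 <- drop_residues(lists1, s, res_id[decision == "pruned_gradient"])
    }
  }
  report <- cbind(pr, mean_grad = mean_grad, decision = decision)
  n_before <- sum(vapply(lists, function(x) nrow(x$restraints), 0L))
  n_after <- sum(vapply(lists1, function(x) nrow(x$restraints), 0L))
  attr(report, "removed") <- n_before - n_after
  class(report) <- c("prune_report", class(report))
  list(lists = if (single) lists1[[1]] else lists1, report = report)
}

drop_residues <- function(lists, s, res_ids) {
  if (!length(res_ids)) return(lists)
  rk <- residue_key(s$atoms)
  lapply(lists, function(rl) {
    r <- rl$restraints
    if (!nrow(r)) return(rl)
    bad <- rk[r$i1] %in% res_ids | rk[r$j1] %in% res_ids
    rl$restraints <- r[!bad, , drop = FALSE]
    rownames(rl$restraints) <- NULL
    rl
  })
}

#' Export a prune report
#'
#' @param report a `prune_report` from [prune_restraints()].
#' @param path output path (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_prune_report <- function(report, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(as.data.frame(report), path, digits = NA,
                         auto_unbox = TRUE)
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
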