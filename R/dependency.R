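#' Conditional response probabilities given previous-trial outcomes
#'
#' Builds the sequential-dependency "tree": the probability of a "yes"
#' response on the current trial conditioned on the outcome of the previous
#' trial (depth 1) and optionally also the trial before that (depth 2),
#' separately for signal and no-signal current trials and, when
#' `group_by_level = TRUE`, per signal level. Conditional frequencies are
#' computed within each session first and then averaged, unweighted, across
#' sessions with at least one qualifying trial; pooled trial counts are
#' carried alongside for the contingency tests.
#'
#' Because an error is followed by a correction trial repeating the same
#' stimulus, a signal trial can never follow a false alarm when correction
#' trials are in use; that conditioning path is simply absent from the tree.
#' Centre-reward trials are removed before sequencing.
#'
#' @param trials A `session_block` or trial-log `data.frame`.
#' @param depth 1 or 2 previous trials to condition on.
#' @param group_by_level Split current signal trials by level? No-signal
#'   trials take their session's level when the session has a single signal
#'   level (Method of Limits) and are pooled otherwise.
#' @param noise_level Masker level (dB SPL) used to attach SNR values;
#'   taken from the block when one is supplied.
#' @return An object of class `dependency_tree`: a list with `nodes` (a
#'   `data.frame` with `trial_type`, `level`, `snr`, `prev1`, `prev2`,
#'   `p_yes`, `n_sessions`, `n_trials`, `n_yes`; `prev1`/`prev2` are `NA`
#'   for marginal nodes), `depth`, and `comparisons` (populated by
#'   [test_dependencies()]).
#' @export
build_dependency_tree <- function(trials, depth = 1L,
                                  group_by_level = TRUE,
                                  noise_level = NA_real_) {
  if (inherits(trials, "session_block")) {
    if (is.na(noise_level)) noise_level <- trials$noise_level
    trials <- trials$trials
  }
  check_trial_log(trials)
  stopifnot(depth %in% c(1L, 2L))
  t <- trials[!trials$centre_reward, , drop = FALSE]
  if (nrow(t) == 0L) stop("no trials left after exclusions")

  rows <- lapply(split(t, t$session_id), function(d) {
    d <- d[order(d$trial_index), , drop = FALSE]
    n <- nrow(d)
    if (n <= depth) return(NULL)
    i <- seq.int(depth + 1L, n)
    sess_level <- unique(d$level[d$trial_type == "signal"])
    lvl <- if (!group_by_level) NA_real_
    else ifelse(d$trial_type[i] == "signal", d$level[i],
                if (length(sess_level) == 1L) sess_level else NA_real_)
    data.frame(session_id = d$session_id[1],
               trial_type = d$trial_type[i],
               level = lvl,
               prev1 = d$outcome[i - 1L],
               prev2 = if (depth == 2L) d$outcome[i - 2L] else NA_character_,
               yes = d$response[i] == "yes",
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  if (is.null(long)) stop("sessions are too short for the requested depth")

  node_levels <- function(d) {
    # per-session proportions, then unweighted across-session mean
    per <- stats::aggregate(yes ~ session_id, d, mean)
    data.frame(p_yes = mean(per$yes), n_sessions = nrow(per),
               n_trials = nrow(d), n_yes = sum(d$yes))
  }
  build <- function(d, prev1, prev2) {
    keys <- interaction(d$trial_type, d$level, drop = FALSE)
    grp <- split(d, list(d$trial_type, as.character(d$level)), drop = TRUE,
                 sep = "\r")
    out <- lapply(names(grp), function(k) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      cbind(data.frame(trial_type = parts[1],
                       level = suppressWarnings(as.numeric(parts[2])),
                       prev1 = prev1, prev2 = prev2,
                       stringsAsFactors = FALSE),
            node_levels(grp[[k]]))
    })
    do.call(rbind, out)
  }
  long$level[is.na(long$level)] <- NaN  # keep pooled groups in split()

  nodes <- build(long, NA_character_, NA_character_)
  for (p1 in unique(long$prev1)) {
    d1 <- long[long$prev1 == p1, , drop = FALSE]
    nodes <- rbind(nodes, build(d1, p1, NA_character_))
    if (depth == 2L) {
      for (p2 in unique(d1$prev2)) {
        d2 <- d1[d1$prev2 == p2, , drop = FALSE]
        nodes <- rbind(nodes, build(d2, p1, p2))
      }
    }
  }
  nodes$level[is.nan(nodes$level)] <- NA_real_
  nodes$snr <- nodes$level - noise_level
  nodes <- nodes[order(nodes$trial_type, nodes$level, nodes$prev1,
                       nodes$prev2, na.last = FALSE), ,
                 drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes[, c("trial_type", "level", "snr", "prev1",
                                   "prev2", "p_yes", "n_sessions",
                                   "n_trials", "n_yes")],
                 depth = depth, group_by_level = group_by_level,
                 noise_level = noise_level, comparisons = NULL),
            class = "dependency_tree")
}

#' @export
print.dependency_tree <- function(x, ...) {
  cat(sprintf("Dependency tree (depth %d): %d nodes\n", x$depth,
              nrow(x$nodes)))
  print(x$nodes, row.names = FALSE, digits = 3)
  if (!is.null(x$comparisons)) {
    cat("\nAfter-hit vs after-CR comparisons:\n")
    print(x$comparisons, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Chi-squared tests of sequential dependencies
#'
#' For every current-trial condition (trial type by level), tests whether
#' the yes/no counts after a hit differ from those after a correct
#' rejection with a 2x2 chi-squared test (no continuity correction). With a
#' depth-2 tree, the two-back outcome is additionally tested within each
#' one-back branch. Holm-Bonferroni correction is applied within each
#' family, one family per current trial type (the per-panel convention).
#' Cells with any expected count below 5 are flagged.
#'
#' @param tree A [build_dependency_tree()] result.
#' @param branches The pair of conditioning outcomes compared (after-hit vs
#'   after-correct-rejection by default).
#' @return The tree with its `comparisons` element set: a `data.frame` with
#'   one row per comparison (`trial_type`, `level`, `within` for two-back
#'   comparisons, counts, `chisq`, `df`, `p`, `p_adj`,
#'   `low_expected_counts`).
#' @export
test_dependencies <- function(tree,
                              branches = c("hit", "correct_rejection")) {
  stopifnot(inherits(tree, "dependency_tree"), length(branches) == 2L)
  nd <- tree$nodes

  one_test <- function(sub, label_within) {
    a <- sub[sub$branch == branches[1], , drop = FALSE]
    b <- sub[sub$branch == branches[2], , drop = FALSE]
    if (nrow(a) != 1L || nrow(b) != 1L) return(NULL)
    m <- rbind(c(a$n_yes, a$n_trials - a$n_yes),
               c(b$n_yes, b$n_trials - b$n_yes))
    if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) return(NULL)
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    data.frame(trial_type = a$trial_type, level = a$level,
               within = label_within,
               p_yes_1 = a$p_yes, p_yes_2 = b$p_yes,
               n_1 = a$n_trials, n_2 = b$n_trials,
               chisq = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value,
               low_expected_counts = any(ct$expected < 5),
               stringsAsFactors = FALSE)
  }

  res <- list()
  # one-back comparisons: prev1 in branches, prev2 marginal
  d1 <- nd[!is.na(nd$prev1) & is.na(nd$prev2) & nd$prev1 %in% branches, ,
           drop = FALSE]
  d1$branch <- d1$prev1
  for (s in split(d1, list(d1$trial_type, d1$level), drop = TRUE))
    res[[length(res) + 1L]] <- one_test(s, NA_character_)
  # two-back comparisons within each one-back branch
  if (tree$depth == 2L) {
    d2 <- nd[!is.na(nd$prev2) & nd$prev2 %in% branches, , drop = FALSE]
    d2$branch <- d2$prev2
    for (s in split(d2, list(d2$trial_type, d2$level, d2$prev1),
                    drop = TRUE))
      res[[length(res) + 1L]] <- one_test(s, s$prev1[1])
  }
  cmp <- do.call(rbind, res)
  if (is.null(cmp)) {
    tree$comparisons <- NULL
    return(tree)
  }
  cmp$p_adj <- NA_real_
  for (fam in unique(cmp$trial_type)) {
    i <- cmp$trial_type == fam
    cmp$p_adj[i] <- stats::p.adjust(cmp$p[i], method = "holm")
  }
  rownames(cmp) <- NULL
  tree$comparisons <- cmp
  tree
}

#' Level dependence of the sequential effect
#'
#' Regresses the after-correct-rejection minus after-hit difference in
#' P(yes) on SNR by ordinary least squares over all per-level points in the
#' tree, returning the slope (per dB) and the regression F statistic. A
#' negative slope reproduces the signature that choice-history effects grow
#' as the signal becomes harder to detect.
#'
#' @param tree A depth-1 or depth-2 [build_dependency_tree()] with SNR
#'   information (`noise_level` supplied when it was built).
#' @param trial_types Current-trial types whose points enter the
#'   regression.
#' @return A list: `slope` (per dB), `intercept`, `f_statistic`, `p_value`,
#'   `points` (the per-level differences), and the fitted `lm` object.
#' @export
dependency_slope <- function(tree,
                             trial_types = c("signal", "nosignal")) {
  stopifnot(inherits(tree, "dependency_tree"))
  nd <- tree$nodes
  d1 <- nd[!is.na(nd$prev1) & is.na(nd$prev2) & !is.na(nd$level) &
             nd$trial_type %in% trial_types, , drop = FALSE]
  pts <- do.call(rbind, lapply(
    split(d1, list(d1$trial_type, d1$level), drop = TRUE),
    function(s) {
      cr <- s$p_yes[s$prev1 == "correct_rejection"]
      hh <- s$p_yes[s$prev1 == "hit"]
      if (length(cr) != 1L || length(hh) != 1L) return(NULL)
      data.frame(trial_type = s$trial_type[1], level = s$level[1],
                 snr = s$snr[1], diff = cr - hh, stringsAsFactors = FALSE)
    }))
  if (is.null(pts) || nrow(pts) < 3L)
    stop("need at least 3 per-level difference points for the regression")
  fit <- stats::lm(diff ~ snr, data = pts)
  fs <- summary(fit)$fstatistic
  list(slope = unname(stats::coef(fit)["snr"]),
       intercept = unname(stats::coef(fit)[1]),
       f_statistic = unname(fs["value"]),
       p_value = unname(stats::pf(fs["value"], fs["numdf"], fs["dendf"],
                                  lower.tail = FALSE)),
       points = pts, fit = fit)
}
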