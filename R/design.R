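#' Build a think/no-think suppression design skeleton
#'
#' Lays out the no-think trials of a virtual TNT experiment: `n_items`
#' word-object pairs, each cued `reps_per_item` times in total, spread evenly
#' over `n_sessions` sessions. Under the defaults (18 items, 8 repetitions,
#' 4 sessions) this yields the canonical 144 suppression trials with every
#' item cued twice per session. Within a session the item order is a seeded
#' pseudo-random permutation with immediate item repetitions avoided where
#' possible.
#'
#' @param n_items number of no-think word-object pairs.
#' @param reps_per_item total number of cues per item across the experiment.
#' @param n_sessions number of TNT sessions; `n_items * reps_per_item` must
#'   be divisible by `n_sessions`, and the per-session trial count by
#'   `n_items`.
#' @param seed integer seed controlling the within-session ordering;
#'   `NULL` leaves the RNG state alone.
#' @return a data frame with columns `trial`, `session`, `item_id` and no
#'   outcomes; one row per no-think trial in chronological order.
#' @examples
#' d <- tnt_design(seed = 1)
#' nrow(d)                       # 144
#' table(table(d$item_id))       # every item cued 8 times
#' @export
tnt_design <- function(n_items = 18, reps_per_item = 8, n_sessions = 4,
                       seed = NULL) {
  stopifnot(n_items >= 1, reps_per_item >= 1, n_sessions >= 1)
  n_trials <- n_items * reps_per_item
  if (n_trials %% n_sessions != 0)
    stop("items x repetitions (", n_trials, ") not divisible into ",
         n_sessions, " sessions")
  per_session <- n_trials / n_sessions
  if (per_session %% n_items != 0)
    stop("per-session trial count (", per_session,
         ") is not a multiple of the item count")
  reps_in_session <- per_session / n_items
  .check_seed(seed)
  items <- sprintf("item%02d", seq_len(n_items))
  order_session <- function() {
    x <- rep(items, reps_in_session)
    x <- sample(x)
    if (length(x) > 1) {
      for (pass in 1:5) {               # repair immediate repetitions
        dup <- which(x[-1] == x[-length(x)]) + 1L
        if (!length(dup)) break
        for (i in dup) {
          ok <- which(x != x[i - 1] & seq_along(x) != i &
                        (seq_along(x) == 1L | x[pmax(seq_along(x) - 1, 1)] != x[i]))
          if (length(ok)) {
            j <- ok[sample.int(length(ok), 1)]
            tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
          }
        }
      }
    }
    x
  }
  item_id <- unlist(lapply(seq_len(n_sessions), function(s) order_session()),
                    use.names = FALSE)
  data.frame(trial = seq_len(n_trials),
             session = rep(seq_len(n_sessions), each = per_session),
             item_id = item_id,
             stringsAsFactors = FALSE)
}

#' Session-wise reference intrusion profile
#'
#' Packaged synthetic target used by the falsification and
#' suppression-tuning routines: the proportion of intrusions starts at
#' chance (0.5, participants cannot yet predict their own control success)
#' and declines across the four sessions toward 0.30 as suppression takes
#' hold. The cohort's real profile is not redistributable, so this is a
#' synthetic stand-in with the same qualitative shape.
#'
#' @return numeric vector of length 4 of per-session intrusion proportions.
#' @export
tnt_target_profile <- function() c(0.50, 0.42, 0.35, 0.30)
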