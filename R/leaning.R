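#' Tweet-level leaning value
#'
#' Mean of the non-neutral (non-zero) hashtag alignment scores of one
#' tweet. A tweet whose hashtags are all neutral carries no signal and is
#' excluded (`NA`).
#'
#' @param hashtag_values Integer scores in \{-3, -1, 0, +1, +3\}.
#' @return Mean score (`C_t`) or `NA_real_` when only neutral tags.
#' @examples
#' tweet_value(c(3, 1)) # 2
#' @export
tweet_value <- function(hashtag_values) {
  check_hashtag_values(hashtag_values)
  v <- hashtag_values[hashtag_values != 0]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' User-level leaning value
#'
#' Mean of a user's defined tweet values; lies in \[-3, 3\].
#'
#' @param tweet_values Numeric tweet values (`NA` entries, from all-neutral
#'   tweets, are dropped).
#' @return Mean (`C_u`), or `NA_real_` when the user has no scorable
#'   tweet (such users are excluded upstream).
#' @export
user_value <- function(tweet_values) {
  v <- tweet_values[!is.na(tweet_values)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Normalize a leaning score to the opinion scale
#'
#' Linear map from \[-3, 3\] to \[0, 1\]: -3 -> 0, 0 -> 0.5, +3 -> 1.
#'
#' @param C_u Leaning score(s) in \[-3, 3\].
#' @return Opinion value(s) in \[0, 1\].
#' @export
normalize_leaning <- function(C_u) {
  if (any(!is.finite(C_u)) || any(C_u < -3 | C_u > 3))
    stop("C_u must lie in [-3, 3]")
  (C_u + 3) / 6
}

#' Discretize a normalized leaning into a stance label
#'
#' `Pro` when the normalized leaning is <= 0.4, `Against` when >= 0.6,
#' `Neutral` otherwise. The three bands partition \[0, 1\] with no gaps.
#'
#' @param opinion Normalized leaning(s) in \[0, 1\].
#' @return Character vector of labels.
#' @export
discretize_leaning <- function(opinion) {
  check_opinion(opinion, "opinion")
  ifelse(opinion <= 0.4, "Pro", ifelse(opinion >= 0.6, "Against", "Neutral"))
}

#' Faction-average media opinions
#'
#' Mean opinion of each stance faction, in the order Pro, Neutral,
#' Against — usable directly as a media landscape (on the real data these
#' averages were 0.28, 0.49 and 0.87). Empty factions are omitted with a
#' warning.
#'
#' @param opinions Normalized opinions in \[0, 1\].
#' @param labels Stance labels (`"Pro"`, `"Neutral"`, `"Against"`).
#' @return A [media_landscape()] of per-faction means.
#' @export
faction_media_opinions <- function(opinions, labels) {
  if (length(opinions) != length(labels))
    stop("opinions and labels must have equal length")
  check_opinion(opinions, "opinions")
  out <- numeric(0)
  for (f in c("Pro", "Neutral", "Against")) {
    ix <- labels == f
    if (any(ix)) out <- c(out, mean(opinions[ix]))
    else warning("empty faction '", f, "' omitted from the landscape")
  }
  media_landscape(out)
}

#' Leaning-ingestion pipeline
#'
#' Turns a hashtag annotation table into per-user opinion records:
#' tweet values ([tweet_value()]) are averaged per user
#' ([user_value()]), normalized ([normalize_leaning()]) and discretized
#' ([discretize_leaning()]). Users with no scorable tweet are excluded
#' and counted in the `excluded_users` attribute.
#'
#' @param annotations Data.frame with columns `tweet_id`, `user_id`,
#'   `hashtag`, `class_value` (scores in \{-3, -1, 0, +1, +3\}).
#' @return Data.frame with one row per retained user: `user_id`, `C_u`,
#'   `opinion`, `label`; attribute `excluded_users` gives the number of
#'   users dropped for lack of scorable tweets.
#' @export
user_leanings <- function(annotations) {
  need <- c("tweet_id", "user_id", "hashtag", "class_value")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  check_hashtag_values(annotations$class_value)
  ct <- vapply(split(annotations$class_value, annotations$tweet_id),
               tweet_value, numeric(1))
  tweet_user <- vapply(split(annotations$user_id, annotations$tweet_id),
                       function(u) as.character(u[1]), character(1))
  cu <- vapply(split(unname(ct), tweet_user), user_value, numeric(1))
  excluded <- sum(is.na(cu))
  if (excluded)
    message(excluded, " user(s) excluded: no tweet with non-neutral hashtags")
  cu <- cu[!is.na(cu)]
  opinion <- normalize_leaning(cu)
  out <- data.frame(user_id = names(cu), C_u = unname(cu),
                    opinion = unname(opinion),
                    label = discretize_leaning(unname(opinion)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded_users") <- excluded
  out
}

#' Synthetic hashtag-annotation table
#'
#' Seeded generator of an annotation table with a configurable faction
#' mix, for exercising the leaning pipeline without real data. Each user
#' authors `tweets_per_user` tweets of `tags_per_tweet` hashtags; a
#' pro-faction user draws tags mostly from \{-3, -1\}, an against-faction
#' user from \{+1, +3\}, a neutral user from \{-1, 0, +1\}, with a
#' sprinkling of neutral tags everywhere.
#'
#' @param n_users Number of users.
#' @param prop Length-3 faction proportions (pro, neutral, against);
#'   normalized internally.
#' @param tweets_per_user,tags_per_tweet Table shape (defaults 3 and 2).
#' @param seed Optional integer seed.
#' @return Data.frame with columns `tweet_id`, `user_id`, `hashtag`,
#'   `class_value` and a `faction` column carrying the generating truth.
#' @export
synthetic_annotations <- function(n_users, prop = c(0.4, 0.2, 0.4),
                                  tweets_per_user = 3L, tags_per_tweet = 2L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prop <- prop / sum(prop)
  faction <- sample(c("pro", "neutral", "against"), n_users,
                    replace = TRUE, prob = prop)
  pools <- list(pro = c(-3, -3, -1, 0), against = c(3, 3, 1, 0),
                neutral = c(-1, 0, 0, 1))
  rows <- list()
  tid <- 0L
  for (u in seq_len(n_users)) {
    for (tw in seq_len(tweets_per_user)) {
      tid <- tid + 1L
      vals <- sample(pools[[faction[u]]], tags_per_tweet, replace = TRUE)
      rows[[tid]] <- data.frame(
        tweet_id = sprintf("t%05d", tid),
        user_id = sprintf("u%04d", u),
        hashtag = sprintf("tag%05d_%d", tid, seq_len(tags_per_tweet)),
        class_value = vals,
        faction = faction[u],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

check_hashtag_values <- function(v) {
  ok <- v %in% c(-3, -1, 0, 1, 3)
  if (!all(ok))
    stop("hashtag class value outside {-3, -1, 0, +1, +3}: ",
         paste(unique(v[!ok]), collapse = ", "))
  invisible(TRUE)
}
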