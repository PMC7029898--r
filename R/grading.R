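# Damage grading: a k-nearest-neighbour vote over the single tailing-factor
# feature (Euclidean distance degenerates to |dt_f|), against the ordinal
# Scu 1-4 cuticle damage scale (Scu 1 least damaged, Scu 4 = cuticle absent).
# The classifier ignores the ordering, as a majority vote does; summaries can
# report the ordinal confusion distance as a diagnostic.

#' Ordered damage grade levels
#' @export
scu_grades <- function() c("Scu 1", "Scu 2", "Scu 3", "Scu 4")

#' Stratified 50/50 train/test split
#'
#' Splits damage records into halves containing the same number of images per
#' condition (exploded / control). When a condition has an odd count the extra
#' record goes to training (with a warning). Deterministic for a fixed seed.
#'
#' @param records data frame with at least a `condition` column.
#' @param seed integer seed controlling the randomization.
#' @return List with data frames `train` and `test`.
#' @export
split_train_test <- function(records, seed) {
  counts <- table(records$condition)
  if (any(counts < 2)) {
    stop("each condition needs at least 2 records to split; got: ",
         paste(names(counts), counts, sep = "=", collapse = ", "), call. = FALSE)
  }
  if (any(counts %% 2 == 1)) {
    warning("odd record count in condition(s) ",
            paste(names(counts)[counts %% 2 == 1], collapse = ", "),
            "; extra record assigned to training", call. = FALSE)
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(records)), records$condition), function(idx) {
      idx <- sample(idx)
      idx[seq_len(ceiling(length(idx) / 2))]
    }), use.names = FALSE)
  })
  list(
    train = records[sort(train_idx), , drop = FALSE],
    test = records[setdiff(seq_len(nrow(records)), train_idx), , drop = FALSE]
  )
}

#' Fit a kNN damage-grade model on tailing factors
#'
#' @param tailing_factor numeric vector of finite, positive training values.
#' @param grade character/factor vector of damage grades, same length.
#' @param k number of neighbours, default 3, `k <= length(tailing_factor)`.
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(tailing_factor, grade, k = 3) {
  tailing_factor <- as.numeric(tailing_factor)
  grade <- as.character(grade)
  if (length(tailing_factor) != length(grade)) {
    stop("`tailing_factor` and `grade` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(tailing_factor)) || any(tailing_factor <= 0)) {
    stop("training tailing factors must be finite and positive", call. = FALSE)
  }
  if (k < 1 || k > length(tailing_factor)) {
    stop("`k` must satisfy 1 <= k <= number of training records", call. = FALSE)
  }
  structure(list(tailing_factor = tailing_factor, grade = grade, k = as.integer(k)),
            class = "knn_model")
}

#' Predict damage grade by k-nearest-neighbour vote
#'
#' For each query tailing factor, the k nearest training values (by |dt_f|)
#' vote; the predicted grade is the majority class and the probability is
#' `winning votes / k`. A vote tie is broken by the class of the nearest
#' neighbour among the tied classes (reported via a message).
#'
#' @param model a [knn_fit()] model.
#' @param tailing_factor numeric vector of query values.
#' @return Data frame with columns `predicted_grade` and `probability`.
#' @export
knn_predict <- function(model, tailing_factor) {
  k <- model$k
  out <- lapply(as.numeric(tailing_factor), function(q) {
    ord <- order(abs(model$tailing_factor - q))
    nb <- model$grade[ord[seq_len(k)]]
    votes <- table(nb)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      winner <- nb[match(TRUE, nb %in% top)]
      message("kNN vote tie at query ", signif(q, 5),
              "; broken by nearest neighbour (", winner, ")")
    } else {
      winner <- top
    }
    data.frame(predicted_grade = winner,
               probability = as.numeric(votes[winner]) / k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate a kNN model on a labelled test set
#'
#' @param model a [knn_fit()] model.
#' @param test data frame with columns `tailing_factor` and `grade` (plus any
#'   identifier columns, which are carried through).
#' @return List with `accuracy` (correct / total) and `table`, the test data
#'   frame extended with `predicted_grade` and `probability`.
#' @export
evaluate <- function(model, test) {
  if (nrow(test) == 0L) stop("test set is empty", call. = FALSE)
  pred <- knn_predict(model, test$tailing_factor)
  tab <- cbind(test, pred)
  list(accuracy = mean(tab$predicted_grade == tab$grade), table = tab)
}

#' Agreement between true and predicted grades
#'
#' @param grade,predicted_grade character vectors of equal length.
#' @return List with `accuracy`, `n_correct`, `n_disagree` and `n`.
#' @export
grading_accuracy <- function(grade, predicted_grade) {
  stopifnot(length(grade) == length(predicted_grade))
  ok <- as.character(grade) == as.character(predicted_grade)
  list(accuracy = mean(ok), n_correct = sum(ok), n_disagree = sum(!ok), n = length(ok))
}

#' Pearson correlation screen with t-test
#'
#' Product-moment correlation `r`, with `t = r * sqrt(df / (1 - r^2))`,
#' `df = n - 2`, and the two-sided p-value from the t distribution — the
#' screen used to select which brightness metric tracks the SEM damage grade.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @return List with `r`, `t`, `p` and `df`.
#' @export
pearson_screen <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Per-hair tailing-factor summary
#'
#' The mean and spread of tailing factors across the images of one hair
#' describe the severity and uniformity of its cuticular damage: a larger
#' mean means more damage, a wider range means damage varies along the hair.
#'
#' @param tailing_factor numeric vector of the hair's per-image values.
#' @return List with `mean`, `sd` (n-1 denominator; 0 with a warning when only
#'   one record), `min`, `max`, `n`.
#' @export
summarize_sample <- function(tailing_factor) {
  tf <- as.numeric(tailing_factor)
  if (length(tf) < 1L) stop("need at least one record", call. = FALSE)
  s <- if (length(tf) == 1L) {
    warning("standard deviation undefined for a single record; reported as 0",
            call. = FALSE)
    0
  } else {
    stats::sd(tf)
  }
  list(mean = mean(tf), sd = s, min = min(tf), max = max(tf), n = length(tf))
}

#' Published kNN test-set table
#'
#' The 16-row labelled test set (hair sample, condition, SEM damage grade,
#' tailing factor at f = 0.02, 3-NN predicted grade and vote probability)
#' shipped with the package for regression tests of the grading module.
#' Blank probabilities in the source table are unanimous 3-NN votes (= 1).
#'
#' @return Data frame with columns `sample_id`, `condition`, `grade`,
#'   `tailing_factor`, `predicted_grade`, `probability`.
#' @export
table1_test_set <- function() {
  path <- system.file("extdata", "table1_test_set.csv", package = "hairsem",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character"))
}
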