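#' Build the trial schedule of a Mooney disambiguation session
#'
#' Schedules one subject's session. Image sets enter the experiment in an
#' introduction run, where the Mooney image is shown pre-disambiguation; in the
#' following run the matching grayscale image is presented and the same Mooney
#' image returns post-disambiguation. With `sets_per_run = s` sets entering per
#' run, every full-run block holds `s` grayscale trials followed by `2s` Mooney
#' trials in randomized order and the same `2s` Mooney trials re-randomized
#' (15 trials for the default `s = 3`). Each block is presented three times per
#' run. The first and last runs are half runs: the first holds only the first
#' pre-disambiguation Mooney images, the last only the final grayscale and
#' post-disambiguation trials. Over the session each Mooney image is presented
#' exactly 6 times pre- and 6 times post-disambiguation and each grayscale
#' image exactly 3 times.
#'
#' Catch sets are scheduled identically but their "grayscale" image does not
#' match the Mooney image content; they control for repetition effects.
#'
#' @param n_real_sets number of real (matching) image sets; default 33.
#' @param n_catch_sets number of catch (non-matching) sets; default 6.
#' @param n_runs number of runs including the two half runs; default 14.
#'   `n_real_sets + n_catch_sets` must be divisible by `n_runs - 1`.
#' @param seed integer seed controlling trial-order randomization and the
#'   assignment of sets to introduction runs.
#' @param set_assignment optional integer vector of length
#'   `n_real_sets + n_catch_sets` giving the introduction run (1 ..
#'   `n_runs - 1`) of each set, exactly `sets_per_run` sets per run. Default:
#'   seeded random assignment.
#'
#' @return A tibble of class `mooney_design`, one row per trial, with columns
#'   `run`, `block`, `trial_in_block`, `trial`, `set_id`, `image_id`,
#'   `image_type` (`"mooney"` or `"grayscale"`), `stage` (`"pre"`, `"post"`, or
#'   `NA` for grayscale trials), `set_type` (`"real"` or `"catch"`), and
#'   `presentation` (presentation counter per image and stage).
#' @examples
#' d <- build_design(n_real_sets = 4, n_catch_sets = 0, n_runs = 5, seed = 1)
#' dplyr::count(d, image_type, stage)
#' @export
build_design <- function(n_real_sets = 33, n_catch_sets = 6, n_runs = 14,
                         seed = 1, set_assignment = NULL) {
  stopifnot(n_real_sets >= 1, n_runs >= 2, n_catch_sets >= 0)
  n_sets <- n_real_sets + n_catch_sets
  if (n_sets %% (n_runs - 1) != 0) {
    abort(sprintf(
      "infeasible design: %d image sets cannot be divided over %d introduction runs",
      n_sets, n_runs - 1
    ))
  }
  s <- n_sets %/% (n_runs - 1)

  set_id <- sprintf("s%02d", seq_len(n_sets))
  set_type <- c(rep("real", n_real_sets), rep("catch", n_catch_sets))
  # grayscale image ids: matching content for real sets, non-matching for catch
  gray_id <- ifelse(set_type == "real", paste0("g", set_id), paste0("x", set_id))

  with_seed(seed, {
    if (is.null(set_assignment)) {
      set_assignment <- sample(rep(seq_len(n_runs - 1), each = s))
    }
    stopifnot(
      length(set_assignment) == n_sets,
      all(table(factor(set_assignment, levels = seq_len(n_runs - 1))) == s)
    )

    rows <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      new_sets <- which(set_assignment == r)        # pre-disambiguation here
      old_sets <- which(set_assignment == r - 1L)   # disambiguated here
      blocks <- lapply(1:3, function(b) {
        gray <- if (length(old_sets)) {
          # sample.int avoids base sample()'s scalar expansion when one set
          # enters per run
          tibble::tibble(
            set = old_sets[sample.int(length(old_sets))],
            image_type = "grayscale", stage = NA_character_
          )
        } else NULL
        mooney_sets <- c(
          rep(old_sets, 1L), # post
          rep(new_sets, 1L)  # pre
        )
        mooney_stage <- c(
          rep("post", length(old_sets)), rep("pre", length(new_sets))
        )
        ord1 <- sample(seq_along(mooney_sets))
        ord2 <- sample(seq_along(mooney_sets))
        mooney <- tibble::tibble(
          set = mooney_sets[c(ord1, ord2)],
          image_type = "mooney",
          stage = mooney_stage[c(ord1, ord2)]
        )
        out <- dplyr::bind_rows(gray, mooney)
        out$block <- b
        out
      })
      run_tbl <- dplyr::bind_rows(blocks)
      run_tbl$run <- r
      rows[[r]] <- run_tbl
    }
    design <- dplyr::bind_rows(rows)
  })

  design <- design |>
    dplyr::group_by(.data$run, .data$block) |>
    dplyr::mutate(trial_in_block = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      trial = dplyr::row_number(),
      set_id = !!set_id[design$set],
      set_type = !!set_type[design$set],
      image_id = !!ifelse(design$image_type == "grayscale",
        gray_id[design$set], set_id[design$set]
      )
    ) |>
    dplyr::group_by(.data$image_id, .data$stage) |>
    dplyr::mutate(presentation = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(
      "run", "block", "trial_in_block", "trial", "set_id", "image_id",
      "image_type", "stage", "set_type", "presentation"
    )

  attr(design, "n_runs") <- n_runs
  attr(design, "sets_per_run") <- s
  attr(design, "sets") <- tibble::tibble(
    set_id = set_id, set_type = set_type, gray_id = gray_id
  )
  attr(design, "seed") <- seed
  class(design) <- c("mooney_design", class(design))
  design
}

#' Simulate subjective recognition and verbal identification
#'
#' Each image set is assigned a latent "recognized" class independently per
#' stage: with probability `p_spontaneous` pre-disambiguation and
#' `p_post_recognize` post-disambiguation for real sets; catch sets use
#' `p_spontaneous` in both stages (the non-matching grayscale conveys no
#' prior). Given the class, each of the six per-stage recognition probes is a
#' Bernoulli draw with rate `p_hit` (recognized class) or `p_miss`
#' (not-recognized class), producing the bimodal count distribution observed
#' behaviorally. Verbal identification is one Bernoulli draw per stage
#' correlated with the class.
#'
#' @param design a [build_design()] schedule.
#' @param p_spontaneous probability that a Mooney image is recognized without
#'   its prior; default 0.34, the observed pre-disambiguation recognized rate.
#' @param p_post_recognize probability that a real image set is recognized
#'   after disambiguation; default 0.87.
#' @param p_hit,p_miss per-presentation response rates within each latent
#'   class.
#' @param p_verbal_hit,p_verbal_miss per-stage verbal identification rates
#'   within each latent class.
#' @param seed integer seed.
#' @return A list of class `mooney_behavior` with tibbles `recognition`
#'   (one row per Mooney presentation: `image_id`, `set_type`, `stage`,
#'   `presentation`, `recognized`) and `verbal` (one row per image and stage:
#'   `image_id`, `set_type`, `stage`, `correct`).
#' @export
simulate_behavior <- function(design, p_spontaneous = 0.34,
                              p_post_recognize = 0.87,
                              p_hit = 0.9, p_miss = 0.1,
                              p_verbal_hit = 0.9, p_verbal_miss = 0.05,
                              seed = 1) {
  stopifnot(
    p_spontaneous >= 0, p_spontaneous <= 1,
    p_post_recognize >= 0, p_post_recognize <= 1
  )
  sets <- attr(design, "sets")
  mooney <- design |>
    dplyr::filter(.data$image_type == "mooney") |>
    dplyr::select("image_id", "set_type", "stage", "presentation")

  with_seed(seed, {
    classes <- tidyr::expand_grid(
      image_id = sets$set_id, stage = c("pre", "post")
    ) |>
      dplyr::left_join(
        dplyr::select(sets, image_id = "set_id", "set_type"),
        by = "image_id"
      ) |>
      dplyr::mutate(
        p_class = ifelse(.data$stage == "post" & .data$set_type == "real",
          p_post_recognize, p_spontaneous
        ),
        recognized_class = rbinom(dplyr::n(), 1, .data$p_class) == 1
      )

    recognition <- mooney |>
      dplyr::left_join(
        dplyr::select(classes, "image_id", "stage", "recognized_class"),
        by = c("image_id", "stage")
      ) |>
      dplyr::mutate(
        recognized = rbinom(
          dplyr::n(), 1,
          ifelse(.data$recognized_class, p_hit, p_miss)
        )
      ) |>
      dplyr::select("image_id", "set_type", "stage", "presentation", "recognized") |>
      dplyr::arrange(.data$image_id, .data$stage, .data$presentation)

    verbal <- classes |>
      dplyr::mutate(
        correct = rbinom(
          dplyr::n(), 1,
          ifelse(.data$recognized_class, p_verbal_hit, p_verbal_miss)
        )
      ) |>
      dplyr::select("image_id", "set_type", "stage", "correct")
  })

  structure(
    list(recognition = recognition, verbal = verbal),
    class = "mooney_behavior"
  )
}

#' Select behaviorally disambiguated image sets
#'
#' Applies the behavioral constraint used for the disambiguation decoders:
#' under the `"subjective"` criterion an image qualifies when it was reported
#' recognized on at most 2 of its 6 pre-disambiguation presentations
#' ("not-recognized") and on at least 4 of 6 post-disambiguation presentations
#' ("recognized"). Under the `"verbal"` criterion the image must be verbally
#' identified incorrectly pre- and correctly post-disambiguation. Catch sets
#' are never selected.
#'
#' @param behavior a [simulate_behavior()] result (or a compatible list with
#'   `recognition` / `verbal` tibbles).
#' @param criterion `"subjective"` or `"verbal"`.
#' @return Character vector of selected `image_id`s (possibly empty, with a
#'   warning).
#' @export
select_disambiguated_sets <- function(behavior,
                                      criterion = c("subjective", "verbal")) {
  criterion <- match.arg(criterion)
  if (criterion == "subjective") {
    counts <- behavior$recognition |>
      dplyr::filter(.data$set_type == "real") |>
      dplyr::group_by(.data$image_id, .data$stage) |>
      dplyr::summarise(n_recognized = sum(.data$recognized), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "stage", values_from = "n_recognized")
    sel <- counts$image_id[counts$pre <= 2 & counts$post >= 4]
  } else {
    verbal <- behavior$verbal |>
      dplyr::filter(.data$set_type == "real") |>
      tidyr::pivot_wider(names_from = "stage", values_from = "correct")
    sel <- verbal$image_id[verbal$pre == 0 & verbal$post == 1]
  }
  if (length(sel) == 0) {
    warn("behavioral selection is empty: no image set meets the criterion")
  }
  sort(sel)
}
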