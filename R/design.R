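#' Generate a communication-session design
#'
#' Produces the 40-trial sequence of one dyadic session: a pre phase in which
#' each of the 8 objects is targeted once in random order, six repetition
#' blocks in which each of the 4 repeated objects is targeted once per block
#' (block order randomized), and a post phase mirroring the pre phase.
#' Repeated targets appear with their 4-object repeated context, control
#' targets with the control context.
#'
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param object_pool Character vector of 8 distinct object ids.
#' @param repeated_ids The 4 ids assigned to the repeated condition; the
#'   remaining 4 form the control set.
#' @return A tibble with one row per trial: `trial_index` (0-based), `phase`,
#'   `block` (1-6 within the repetition phase, otherwise `NA`), `target_id`,
#'   `condition`, and `context` (list-column of 4 object ids).
#' @export
generate_session <- function(seed, object_pool, repeated_ids) {
  if (length(object_pool) != 8 || anyDuplicated(object_pool)) {
    abort("object_pool must contain 8 distinct object ids")
  }
  if (length(repeated_ids) != 4 || !all(repeated_ids %in% object_pool)) {
    abort("repeated_ids must be 4 ids drawn from object_pool (4/4 split)")
  }
  control_ids <- setdiff(object_pool, repeated_ids)
  withr::with_seed(seed, {
    pre <- sample(object_pool)
    blocks <- lapply(1:6, function(b) sample(repeated_ids))
    post <- sample(object_pool)
    des <- tibble(
      trial_index = 0:39,
      phase = c(rep("pre", 8), rep("repetition", 24), rep("post", 8)),
      block = c(rep(NA_integer_, 8), rep(1:6, each = 4), rep(NA_integer_, 8)),
      target_id = c(pre, unlist(blocks), post)
    )
    des$condition <- ifelse(des$target_id %in% repeated_ids, "repeated", "control")
    des$context <- lapply(des$condition, function(cc) {
      if (cc == "repeated") repeated_ids else control_ids
    })
    des
  })
}

#' Yoked recognition sequence
#'
#' A yoked recognition participant views all 40 drawings of a single
#' communication interaction in the order the original viewer saw them.
#'
#' @param interaction A complete [interaction_record()] (40 drawings, one per
#'   trial).
#' @return A 40-row sequence tibble (see [generate_session()] fields plus
#'   `position`, `source_dyad`, `group = "yoked"`).
#' @export
yoked_sequence <- function(interaction) {
  tr <- interaction$trials
  dw <- interaction$drawings
  k <- appearance_index(tr$phase, tr$repetition)
  key_tr <- paste(tr$target_id, tr$phase, k)
  key_dw <- paste(dw$object_id, dw$phase, dw$repetition)
  hit <- match(key_tr, key_dw)
  if (anyNA(hit) || nrow(tr) != 40) {
    missing <- tr$trial_index[is.na(hit)]
    abort(paste0("interaction incomplete; missing drawings for trial(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble(
    position = seq_len(40),
    drawing_id = dw$drawing_id[hit],
    source_dyad = interaction$dyad_id,
    object_id = tr$target_id,
    repetition = k,
    phase = tr$phase,
    condition = tr$condition,
    is_attention_check = FALSE,
    group = "yoked"
  )
}

#' Shuffled recognition sequence
#'
#' A shuffled recognition participant views drawings spliced from 10
#' different interactions: four drawings per source interaction, each kept in
#' the phase/repetition slot it originally occupied. Eight sources are
#' assigned (bijectively, seeded) to the eight repetition-indexed slots of
#' the repeated objects (pre = appearance 1, blocks = 2-7, post = 8); the
#' remaining two sources supply the control-object pre and post drawings.
#'
#' @param interactions List of >= 10 complete [interaction_record()]s sharing
#'   the same object sets and conditions.
#' @param seed Integer seed for the source-to-slot assignment.
#' @return A 40-row sequence tibble with `group = "shuffled"`.
#' @export
shuffled_sequence <- function(interactions, seed) {
  if (length(interactions) < 10) {
    abort("shuffled sequences need at least 10 source interactions")
  }
  template <- yoked_sequence(interactions[[1]])
  withr::with_seed(seed, {
    sources <- sample(interactions, 10)
    rep_sources <- sources[1:8]
    ctl_sources <- sources[9:10]
    # appearance slot k -> source interaction (bijective)
    slot_of <- sample(1:8)
    out <- template
    for (i in seq_len(nrow(out))) {
      if (out$condition[i] == "repeated") {
        src <- rep_sources[[slot_of[out$repetition[i]]]]
      } else {
        src <- ctl_sources[[if (out$phase[i] == "pre") 1 else 2]]
      }
      dw <- src$drawings
      hit <- which(dw$object_id == out$object_id[i] &
                     dw$phase == out$phase[i] &
                     dw$repetition == out$repetition[i])
      if (length(hit) != 1) {
        abort(sprintf("source %s lacks a drawing of %s at %s/appearance %d",
                      src$dyad_id, out$object_id[i], out$phase[i], out$repetition[i]))
      }
      out$drawing_id[i] <- dw$drawing_id[hit]
      out$source_dyad[i] <- src$dyad_id
    }
    out$group <- "shuffled"
    out
  })
}

#' Insert attention checks into a recognition sequence
#'
#' Inserts five identical attention-check trials, one after every eighth
#' non-check trial (so the checks sit at positions 9, 18, 27, 36 and 45 of
#' the final 45-item sequence). `strip_attention_checks()` is the inverse;
#' `attention_check_pass()` implements the inclusion rule (at least four of
#' the five checks answered correctly).
#'
#' @param seq_tbl A 40-row sequence tibble.
#' @param check_item One-row tibble (or list) describing the check trial; its
#'   fields are recycled into the sequence schema.
#' @return A 45-row sequence tibble with `is_attention_check` flags.
#' @export
insert_attention_checks <- function(seq_tbl, check_item) {
  if (nrow(seq_tbl) != 40) abort("expected a 40-item sequence")
  check <- as_tibble(as.list(check_item))
  chunks <- split(seq_tbl, rep(1:5, each = 8))
  out <- dplyr::bind_rows(lapply(chunks, function(ch) {
    row <- ch[1, ]
    for (nm in names(check)) row[[nm]] <- check[[nm]]
    row$is_attention_check <- TRUE
    dplyr::bind_rows(ch, row)
  }))
  out$position <- seq_len(nrow(out))
  out
}

#' @rdname insert_attention_checks
#' @export
strip_attention_checks <- function(seq_tbl) {
  out <- seq_tbl[!seq_tbl$is_attention_check, ]
  out$position <- seq_len(nrow(out))
  out
}

#' @rdname insert_attention_checks
#' @param correct Logical (or 0/1) vector of attention-check responses.
#' @export
attention_check_pass <- function(correct) {
  sum(as.logical(correct)) >= 4
}
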