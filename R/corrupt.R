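#' Minimally corrupt a record so one validation rule fires
#'
#' For every corruptible rule in [validation_rules()] this applies the
#' smallest perturbation that violates exactly that rule — and, thanks
#' to the validator's rule hierarchy, only that rule: for example an
#' interval swap also invalidates the CIGAR-span premise, but
#' CIGAR_SPAN is skipped when its interval is malformed, so INTERVAL
#' alone fires.
#'
#' Perturbations: `TYPE` zeroes a coordinate; `INTERVAL` swaps
#' `v_sequence_start`/`v_sequence_end`; `JUNC_LEN` adds 1 to
#' `junction_length`; `JUNC_AA` appends a residue to `junction_aa`;
#' `CIGAR_SPAN` inflates the first aligned operation of `v_cigar`;
#' `REGION_BOUNDS` pushes `cdr1_end` past the sequence end; `ALN_LEN`
#' drops the last character of `germline_alignment`.
#'
#' @param record a named list or one-row data frame, currently clean
#'   for `rule` and non-null in the fields the rule touches.
#' @param rule a corruptible rule id.
#' @return a list with `record` (the corrupted record, same shape as
#'   the input) and `restore` (the saved original values;
#'   [restore_record()] undoes the corruption exactly).
#' @examples
#' sim <- simulate_dataset(1, seed = 1)
#' bad <- corrupt_record(sim$records[1, ], "INTERVAL")
#' validate_record(bad$record)$rule_id
#' @export
corrupt_record <- function(record, rule) {
  was_df <- is.data.frame(record)
  if (was_df) {
    stopifnot(nrow(record) == 1L)
    rec <- as.list(record)
  } else {
    rec <- record
  }
  rules <- validation_rules()
  if (!rule %in% rules$rule_id[rules$corruptible]) {
    abort_airr(sprintf("'%s' is not a corruptible rule id", rule),
               "airr_domain_error")
  }
  need <- function(fields) {
    missing <- fields[!vlogical(fields, function(f) nn(rec[[f]]))]
    if (length(missing)) {
      abort_airr(sprintf(
        "cannot target %s: field(s) %s are null in this record",
        rule, paste(missing, collapse = ", ")), "airr_domain_error")
    }
  }
  touched <- switch(rule,
    TYPE = {
      need("v_germline_start")
      save <- rec["v_germline_start"]
      rec$v_germline_start <- 0L
      save
    },
    INTERVAL = {
      need(c("v_sequence_start", "v_sequence_end"))
      save <- rec[c("v_sequence_start", "v_sequence_end")]
      if (rec$v_sequence_start == rec$v_sequence_end) {
        rec$v_sequence_start <- rec$v_sequence_end + 1L
      } else {
        tmp <- rec$v_sequence_start
        rec$v_sequence_start <- rec$v_sequence_end
        rec$v_sequence_end <- tmp
      }
      save
    },
    JUNC_LEN = {
      need("junction_length")
      save <- rec["junction_length"]
      rec$junction_length <- rec$junction_length + 1L
      save
    },
    JUNC_AA = {
      need(c("junction", "junction_aa"))
      save <- rec["junction_aa"]
      rec$junction_aa <- paste0(rec$junction_aa, "X")
      save
    },
    CIGAR_SPAN = {
      need("v_cigar")
      save <- rec["v_cigar"]
      ops <- parse_cigar(rec$v_cigar)
      i <- which(ops$op %in% COLUMN_OPS)[1L]
      ops$length[i] <- ops$length[i] + 2L
      rec$v_cigar <- cigar_string(ops)
      save
    },
    REGION_BOUNDS = {
      need(c("sequence", "cdr1_start", "cdr1_end"))
      save <- rec["cdr1_end"]
      rec$cdr1_end <- nchar(rec$sequence) + 3L
      save
    },
    ALN_LEN = {
      need("germline_alignment")
      save <- rec["germline_alignment"]
      rec$germline_alignment <- substr(rec$germline_alignment, 1L,
                                       nchar(rec$germline_alignment) - 1L)
      save
    })
  out <- if (was_df) {
    df <- record
    for (nm in names(rec)) df[[nm]] <- rec[[nm]]
    df
  } else rec
  list(record = out, restore = touched)
}

#' @rdname corrupt_record
#' @param restore the `restore` element returned by [corrupt_record()].
#' @export
restore_record <- function(record, restore) {
  if (is.data.frame(record)) {
    for (nm in names(restore)) record[[nm]] <- restore[[nm]]
  } else {
    record[names(restore)] <- restore
  }
  record
}
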