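# Typed error conditions. Every validation failure gets its own condition
# class so callers (and the CLI) can branch on the failure mode instead of
# parsing message strings.

mq_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(errorCondition(message, ..., class = c(class, "mq_error")))
}

mq_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "mq_warning")))
}

# condition classes in use:
#   mq_missing_column   a required column is absent
#   mq_unknown_id       an event/offspring row references an id not on the roster
#   mq_duplicate_seq    two copulations share (vial, day, seq)
#   mq_bad_day          day or lay_day outside 1..days
#   mq_bad_value        categorical field outside its domain
#   mq_focal_count      a vial without exactly one focal male
#   mq_marker_mismatch  marker inconsistent with role
#   mq_vial_composition a vial without 4 males and 4 females
#   mq_negative_count   negative offspring count
#   mq_no_data          pipeline invoked on an empty dataset
#   mq_degenerate_input zero-variance input where variation is required
#   mq_singular_design  rank-deficient model matrix
#   mq_too_many_predictors  subset enumeration guard (k > 15)
#   mq_incomplete_subsets   commonality input missing subsets
#   mq_single_level     factor with one level where a contrast is needed
#   mq_unknown_vial     vial not present in the dataset
#   mq_bad_param        simulation parameter outside its domain
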