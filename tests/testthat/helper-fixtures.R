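# Hand-built single-vial fixtures. Male ids M1..M4 (M1 = wild-type focal),
# female ids F1..F4; everything else defaults to large flies.

toy_roster <- function(vial = "V1",
                       male_sizes = rep("large", 4),
                       female_sizes = rep("large", 4),
                       focal_size = male_sizes[1]) {
  role <- rep("rival_male", 4)
  role[which(male_sizes == focal_size)[1]] <- "focal_male"
  data.frame(
    id = c(paste0("M", 1:4), paste0("F", 1:4)),
    vial = vial,
    sex = rep(c("male", "female"), each = 4),
    size_class = c(male_sizes, female_sizes),
    marker = c(ifelse(role == "focal_male", "wildtype", "spa"), rep("spa", 4)),
    role = c(role, rep("female", 4)),
    stringsAsFactors = FALSE
  )
}

toy_focal_id <- function(roster) roster$id[roster$role == "focal_male"]

# events from a compact spec: list of c(day, seq, male, female)
toy_events <- function(..., vial = "V1") {
  rows <- list(...)
  if (!length(rows)) {
    return(data.frame(vial = character(), day = integer(), seq = integer(),
                      male_id = character(), female_id = character()))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(vial = vial, day = as.integer(r[[1]]), seq = as.integer(r[[2]]),
               male_id = r[[3]], female_id = r[[4]], stringsAsFactors = FALSE)
  }))
}

# offspring from a compact spec: list of c(female, lay_day, wt, spa)
toy_offspring <- function(..., vial = "V1") {
  rows <- list(...)
  if (!length(rows)) {
    return(data.frame(vial = character(), female_id = character(),
                      lay_day = integer(), count_wildtype = integer(),
                      count_spa = integer()))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(vial = vial, female_id = r[[1]], lay_day = as.integer(r[[2]]),
               count_wildtype = as.integer(r[[3]]),
               count_spa = as.integer(r[[4]]), stringsAsFactors = FALSE)
  }))
}

toy_dataset <- function(events = toy_events(), offspring = toy_offspring(),
                        roster = toy_roster(), design = NULL) {
  suppressWarnings(mating_dataset(roster, events, offspring, design))
}

# fabricated score table for inference tests that need no raw dataset
toy_scores <- function(order_index, paternity_share,
                       repetitive_count = seq_along(order_index),
                       experiment = "M", social = "Hom",
                       focal_size = "large") {
  n <- length(order_index)
  data.frame(
    vial = paste0("V", seq_len(n)),
    experiment = rep_len(experiment, n),
    social = rep_len(social, n),
    treatment = "X",
    focal_size = rep_len(focal_size, n),
    focal_id = "M1",
    paternity_share = paternity_share,
    order_index = order_index,
    repetitive_count = repetitive_count,
    n_eligible_females = 2L,
    n_focal_matings = 3L,
    assortative_count = 1L,
    group_mean_fecundity = 20 + seq_len(n),
    mate_mean_fecundity = 20 + seq_len(n),
    stringsAsFactors = FALSE
  )
}
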