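# Shared fixtures: the default protocol profile and FTE convention are
# loaded once; surveys are built in code, never stored on disk.

default_profile <- default_generation_hd1_profile()
default_convention <- fte_convention()

# One-centre survey collection with sensible defaults, overridable per test.
make_collection <- function(..., metadata = list()) {
  rows <- list(...)
  if (length(rows) == 0L) rows <- list(centre_survey("C1"))
  suppressMessages(survey_collection(do.call(rbind, rows), metadata))
}

# A centre back-solved to an exact coverage fraction of its demand.
centre_at_coverage <- function(coverage, demand = 114, id = "C1",
                               willingness = c(proceduralist = 1, nurse = 1,
                                               facility = 1)) {
  avail <- vapply(resource_classes(), function(r) {
    coverage * needed_fte(demand, default_profile, r, default_convention) /
      willingness[[r]]
  }, numeric(1))
  centre_survey(id, anticipated_patients_per_year = demand,
                resource_availability = avail, willingness = willingness)
}

# Independent brute-force throughput oracle: per-class division written out
# step by step, no shared code with capacity_procedures().
brute_force_capacity <- function(centre, profile, convention,
                                 apply_willingness = TRUE) {
  per_class <- sapply(resource_classes(), function(r) {
    minutes <- 0
    for (i in seq_len(nrow(profile$steps))) {
      if (profile$steps$resource[i] == r) {
        minutes <- minutes + profile$steps$minutes[i] * profile$steps$persons[i]
      }
    }
    if (minutes == 0) return(Inf)
    fte <- centre[[paste0(r, "_fte")]]
    if (apply_willingness) fte <- fte * centre[[paste0(r, "_willingness")]]
    fte * convention$hours_per_year * 60 / minutes
  })
  list(capacity = min(per_class),
       bottleneck = resource_classes()[which.min(per_class)])
}
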