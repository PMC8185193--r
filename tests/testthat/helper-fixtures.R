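# Programmatic fixtures: small CSVs written to tempfiles at test time.

writeDvhFixture <- function(rows) {
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# One differential ovaries DVH per technique for one patient.
simpleDvhRows <- function(patient = "P1", volumes = c(0.2, 0.5, 0.3),
                          doses = c(0, 10, 20), technique = "IFRT",
                          dvh_type = "differential",
                          volume_kind = "relative") {
  data.frame(patient_id = patient, technique = technique,
             organ = "ovaries", dvh_type = dvh_type, dose_gy = doses,
             volume = volumes, volume_kind = volume_kind,
             stringsAsFactors = FALSE)
}

# Hand-built 4-record hormone cohort with easily checked group stats.
handHormoneCohort <- function() {
  data.frame(
    patient_id = c("A", "B", "C", "D"),
    sex = c("female", "female", "male", "male"),
    age_years = c(25, 35, 25, 35),
    chemo = c("ABVD", "2+2", "ABVD", "2+2"),
    rt_field = c("SDRT", "IDRT", "SDRT", "SDRT"),
    fsh_u_per_l = c(4, 16, 2, 8),
    lh_u_per_l = c(3, 9, 3, 27),
    stringsAsFactors = FALSE)
}

# A patient pair whose ovary DVHs are single uniform bins at the given
# doses (0.1 Gy wide around them), for hand-computable survival chains.
uniformDosePair <- function(id, doseIfrt, doseIsrt) {
  mk <- function(tech, z) {
    d <- DifferentialDVH("ovaries", c(z, z + 0.1), 1)
    PlanRecord(id, tech, list(ovaries = d))
  }
  PatientPair(mk("IFRT", doseIfrt), mk("ISRT", doseIsrt))
}
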