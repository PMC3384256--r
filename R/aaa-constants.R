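# Shared vocabulary of the event typology.  Loaded first (file name) so
# every module can build on it at load time.

EVENT_TYPES <- c("Gene_expression", "Transcription", "Protein_catabolism",
                 "Phosphorylation", "Localization", "Binding",
                 "Regulation", "Positive_regulation", "Negative_regulation")
SIMPLE_TYPES <- EVENT_TYPES[1:5]
REGULATION_TYPES <- c("Regulation", "Positive_regulation", "Negative_regulation")
PRIMARY_ROLES <- c("Theme", "Cause")
SECONDARY_ROLES <- c("Site", "CSite", "AtLoc", "ToLoc")

EVENT_GROUPS <- list(
  "Simple Event" = SIMPLE_TYPES,
  "Binding" = "Binding",
  "Regulation" = REGULATION_TYPES,
  "All" = EVENT_TYPES)
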