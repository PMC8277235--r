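# Information-model profiles compared for expressive power. Each profile is a
# named subset of schema attribute names; a gold instance counts as precisely
# represented under a profile iff its annotation fully captures the original
# description and every non-default attribute it carries is in the profile.
# CEM and FHIR subsets are best-effort approximations of the attributes those
# models share with this schema (only assertion, severity and laterality are
# exercised in guideline prose); they are config-driven and replaceable.
profiles:
  - name: phenossu
    attributes: [assertion, frequency, age_specificity, sex_specificity,
                 illness_severity, temporal_pattern, severity, color,
                 sensation, laterality, spatial_pattern, quadrant_pattern]
  - name: cem
    attributes: [assertion, severity, laterality]
  - name: fhir
    attributes: [severity, laterality]
  - name: concept_only
    attributes: []
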