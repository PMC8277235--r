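# Default twelve-attribute schema: one phenotype concept plus five presence,
# four manifestation and three spatial attributes, each with a closed,
# SNOMED-CT-coded value set and per-value trigger-term lexicons.
#
# Defaults ("present" for assertion, "none" elsewhere) are schema-level
# sentinels, not SNOMED annotations, and carry no code. Codes marked
# "best-effort" approximate the intended SNOMED qualifier values and can be
# replaced without code changes; value sets and trigger lexicons are likewise
# user-extensible.
version: "1.0"
attributes:
  # ---- presence ----
  - name: assertion
    code: "408729009"          # finding context (best-effort)
    category: presence
    default: present
    values:
      - label: present
        code: "410515003"      # known present (best-effort)
        triggers: []
      - label: absent
        code: "410516002"      # known absent (best-effort)
        triggers: ["no", "not", "without", "absence of", "denies", "never"]
      - label: possible
        code: "410590009"      # known possible (best-effort)
        triggers: ["may", "might", "possible", "possibly", "suspected",
                   "include", "can occur"]
  - name: frequency
    code: "260864003"          # frequency (best-effort)
    category: presence
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: rare
        code: "84638005"       # best-effort
        triggers: ["rare", "rarely", "uncommon", "infrequent"]
      - label: occasional
        code: "84892002"       # best-effort
        triggers: ["occasionally", "occasional", "sometimes", "in some cases"]
      - label: frequent
        code: "70232002"       # best-effort
        triggers: ["common", "commonly", "frequent", "frequently", "often",
                   "usually", "most patients"]
  - name: age_specificity
    code: "445518008"          # age at onset (best-effort)
    category: presence
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: children
        code: "67822003"       # best-effort
        triggers: ["children", "infants", "pediatric"]
      - label: adults
        code: "133936004"      # best-effort
        triggers: ["adults", "young adults"]
      - label: elderly
        code: "105436006"      # best-effort
        triggers: ["elderly", "older adults"]
  - name: sex_specificity
    code: "429019009"          # best-effort
    category: presence
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: male
        code: "248153007"      # best-effort
        triggers: ["men", "males", "boys"]
      - label: female
        code: "248152002"      # best-effort
        triggers: ["women", "females", "girls"]
  - name: illness_severity
    code: "246112005"          # severity of illness context (best-effort)
    category: presence
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: mild_illness
        code: "255604002"      # best-effort reuse of "mild"
        triggers: ["milder cases", "milder illness"]
      - label: severe_illness
        code: "24484000"       # best-effort reuse of "severe"
        triggers: ["severely ill", "critically ill", "fulminant cases"]
  # ---- manifestation ----
  - name: temporal_pattern
    code: "263502005"          # clinical course (best-effort)
    category: manifestation
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: acute
        code: "373933007"      # best-effort
        triggers: ["sudden onset", "sudden", "acute", "abrupt"]
      - label: chronic
        code: "90734009"
        triggers: ["chronic", "persistent", "long-standing"]
      - label: intermittent
        code: "7087005"        # best-effort
        triggers: ["intermittent", "episodic", "relapsing", "recurrent"]
      - label: gradual
        code: "61751001"       # best-effort
        triggers: ["gradually", "gradual onset", "insidious"]
  - name: severity
    code: "272141005"          # severity
    category: manifestation
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: mild
        code: "255604002"
        triggers: ["mild", "slight"]
      - label: moderate
        code: "6736007"
        triggers: ["moderate", "moderately"]
      - label: severe
        code: "24484000"
        triggers: ["severe", "intense", "extreme"]
  - name: color
    code: "263714004"          # colour (best-effort)
    category: manifestation
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: red
        code: "386713009"      # best-effort
        triggers: ["red", "reddish", "erythematous"]
      - label: yellow
        code: "371244009"      # best-effort
        triggers: ["yellow", "yellowish"]
      - label: purple
        code: "405738005"      # best-effort
        triggers: ["purple", "purpuric"]
      - label: pale
        code: "398979000"      # best-effort
        triggers: ["pale", "pallid"]
  - name: sensation
    code: "276435006"          # best-effort
    category: manifestation
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: sharp
        code: "410704009"      # best-effort
        triggers: ["sharp", "stabbing"]
      - label: dull
        code: "410703003"      # best-effort
        triggers: ["dull", "aching"]
      - label: burning
        code: "90673000"       # best-effort
        triggers: ["burning"]
      - label: itchy
        code: "418290006"      # best-effort
        triggers: ["itchy", "itching", "pruritic"]
  # ---- spatial ----
  - name: laterality
    code: "272741003"          # laterality
    category: spatial
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: unilateral
        code: "66459002"
        triggers: ["unilateral", "one side", "one-sided"]
      - label: bilateral
        code: "51440002"
        triggers: ["bilateral", "both sides"]
  - name: spatial_pattern
    code: "263496004"          # best-effort
    category: spatial
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: localized
        code: "255471001"      # best-effort
        triggers: ["localized", "localised", "confined"]
      - label: generalized
        code: "60132005"       # best-effort
        triggers: ["generalized", "generalised", "widespread", "diffuse"]
  - name: quadrant_pattern
    code: "255549009"          # best-effort
    category: spatial
    default: none
    values:
      - label: none
        code: ""
        triggers: []
      - label: upper_right
        code: "255497008"      # best-effort
        triggers: ["upper right"]
      - label: upper_left
        code: "255496004"      # best-effort
        triggers: ["upper left"]
      - label: lower_right
        code: "255498003"      # best-effort
        triggers: ["lower right"]
      - label: lower_left
        code: "255499006"      # best-effort
        triggers: ["lower left"]
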