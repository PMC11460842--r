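# Default rapid-scoring rubric.
#
# The safety criterion's five characteristics and scores are the published
# ones. The characteristic sets of the other seven criteria were authored
# for this package from the published list of "elements considered" and are
# NON-CANONICAL: edit freely. Characteristics of exclusion (is_exclusion:
# true, score -100) are editable placeholders standing in for the original
# instrument's unpublished exclusion list.
version: "1.0-default"
notes: >
  Safety characteristics are canonical; all other characteristic sets and
  the exclusion placeholders are package-authored defaults.
scale:
  min: -10
  max: 10
  typical: [-5, 5]
  exclusion_sentinel: -100
criteria:
  - id: quality_of_evidence
    name: Quality of evidence
    characteristics:
      - id: qoe_phase3_peer_reviewed
        label: "Peer-reviewed Phase 3 results available, no important limitations"
        score: 4
        is_exclusion: false
      - id: qoe_phase3_preprint
        label: "Phase 3 results available as pre-print or with notable limitations (e.g., limited generalizability)"
        score: 2
        is_exclusion: false
      - id: qoe_phase2
        label: "Phase 2 results only"
        score: 1
        is_exclusion: false
      - id: qoe_unknown
        label: "Unknown or results pending"
        score: 0
        is_exclusion: false
      - id: qoe_early_or_flawed
        label: "Phase 1 / preclinical only, or results with major design flaws"
        score: -2
        is_exclusion: false
      - id: qoe_discontinued
        label: "Development of the therapeutic has been discontinued (exclusion placeholder)"
        score: -100
        is_exclusion: true
  - id: clinical_impact
    name: Clinical impact
    characteristics:
      - id: ci_primary_large
        label: "Large, statistically significant impact on a primary clinical outcome"
        score: 5
        is_exclusion: false
      - id: ci_primary_moderate
        label: "Moderate, statistically significant impact on a primary outcome"
        score: 3
        is_exclusion: false
      - id: ci_secondary_only
        label: "Impact limited to secondary outcomes"
        score: 1
        is_exclusion: false
      - id: ci_unknown
        label: "Unknown or results pending"
        score: 0
        is_exclusion: false
      - id: ci_no_effect
        label: "No statistically significant impact demonstrated"
        score: -3
        is_exclusion: false
      - id: ci_out_of_scope
        label: "Out of scope of the assessment mandate (exclusion placeholder)"
        score: -100
        is_exclusion: true
  - id: safety
    name: Safety data
    characteristics:
      - id: safety_none_significant
        label: "None of potential significance from a Phase 3 trial or real-world evidence (no AEs or mild to moderate AEs; no significant type or number of DIs, warnings and contraindications)"
        score: 2
        is_exclusion: false
      - id: safety_probably_none
        label: "Unknown, but probably no AEs of significance (no AEs or mild to moderate AEs; no significant type or number of DIs, warnings and contraindications)"
        score: 1
        is_exclusion: false
      - id: safety_unknown
        label: "Unknown"
        score: 0
        is_exclusion: false
      - id: safety_serious_warnings
        label: "Serious warnings and precautions or indication restricted because of significant safety concerns"
        score: -2
        is_exclusion: false
      - id: safety_probably_significant
        label: "Unknown, but probably some of significance (at least one of: significant AEs, DIs, warnings or contraindications or a serious AE of particular concern)"
        score: -3
        is_exclusion: false
  - id: patient_preference
    name: Patient preference
    characteristics:
      - id: pp_favourable
        label: "Favourable route, dosing frequency and access (e.g., single-dose oral outpatient therapeutic)"
        score: 3
        is_exclusion: false
      - id: pp_neutral
        label: "Neither clearly favourable nor burdensome"
        score: 1
        is_exclusion: false
      - id: pp_unknown
        label: "Unknown"
        score: 0
        is_exclusion: false
      - id: pp_burdensome
        label: "Burdensome route, frequent dosing or poor access (e.g., repeated infusions)"
        score: -2
        is_exclusion: false
  - id: treatment_alternatives
    name: Availability of authorized treatment alternatives for the same broad target patient population
    characteristics:
      - id: ta_none
        label: "No authorized alternative for the target patient population"
        score: 4
        is_exclusion: false
      - id: ta_one
        label: "One authorized alternative"
        score: 2
        is_exclusion: false
      - id: ta_unknown
        label: "Unknown"
        score: 0
        is_exclusion: false
      - id: ta_several
        label: "Several authorized alternatives"
        score: -2
        is_exclusion: false
  - id: authorization_canada
    name: Authorization status in Canada
    characteristics:
      - id: ac_other_indication
        label: "Authorized in Canada for an indication other than the one being studied"
        score: 2
        is_exclusion: false
      - id: ac_unknown
        label: "Unknown"
        score: 0
        is_exclusion: false
      - id: ac_none
        label: "No authorized indication in Canada"
        score: -1
        is_exclusion: false
  - id: regulatory_other
    name: Regulatory status in other jurisdictions
    characteristics:
      - id: ro_authorized_stringent
        label: "Authorized for the studied indication by a stringent regulatory authority (e.g., United States, Europe, Australia)"
        score: 3
        is_exclusion: false
      - id: ro_under_review
        label: "Under review by at least one stringent regulatory authority"
        score: 1
        is_exclusion: false
      - id: ro_unknown
        label: "Unknown"
        score: 0
        is_exclusion: false
      - id: ro_refused
        label: "Authorization refused by a stringent regulatory authority"
        score: -3
        is_exclusion: false
      - id: ro_withdrawn_safety
        label: "Withdrawn from a market because of serious safety concerns (exclusion placeholder)"
        score: -100
        is_exclusion: true
  - id: domestic_landscape
    name: Domestic therapeutic development landscape
    characteristics:
      - id: dl_strong
        label: "Canadian funding and study sites, or Canadian manufacturer"
        score: 3
        is_exclusion: false
      - id: dl_some
        label: "Some Canadian involvement (past funding or a single study site)"
        score: 1
        is_exclusion: false
      - id: dl_unknown
        label: "Unknown"
        score: 0
        is_exclusion: false
      - id: dl_none
        label: "No Canadian involvement"
        score: -1
        is_exclusion: false
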