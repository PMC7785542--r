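{
  "schema_version": "1.0",
  "profiles": [
    {
      "product_id": "FIX-DHOT-1",
      "name": "synthetic-dhot-like",
      "approval_year": 2018,
      "review_division": "DHOT",
      "designations": [
        "orphan"
      ],
      "indication": "hematologic_malignancy",
      "benefit": {
        "condition_severity": "severe",
        "condition_prevalence": "rare_orphan",
        "treatment_availability": "none_exist",
        "durability": "consistent_substantial",
        "orphan_designation": true,
        "verbatim": null
      },
      "risks": [
        {
          "risk": {
            "term": "neutropenia",
            "severity": "severe",
            "ctcae_grade": null,
            "frequency_band": "high",
            "frequency_percent": null,
            "nonclinical_only": false,
            "resolved_no_risk": false,
            "severity_override": false,
            "verbatim": "neutropenia"
          },
          "mitigations": [
            {
              "kind": "routine_pharmacovigilance",
              "burden_value": 0,
              "verbatim": null
            }
          ]
        },
        {
          "risk": {
            "term": "infusion_reaction",
            "severity": "moderate",
            "ctcae_grade": null,
            "frequency_band": "medium",
            "frequency_percent": null,
            "nonclinical_only": false,
            "resolved_no_risk": false,
            "severity_override": false,
            "verbatim": "infusion reaction"
          },
          "mitigations": [
            {
              "kind": "boxed_warning",
              "burden_value": null,
              "verbatim": null
            },
            {
              "kind": "label_warning_precaution",
              "burden_value": null,
              "verbatim": null
            }
          ]
        }
      ]
    }
  ]
}
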