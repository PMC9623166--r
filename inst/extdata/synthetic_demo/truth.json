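{
  "module_of_otu": {
    "OTU001": 1,
    "OTU002": 1,
    "OTU003": 1,
    "OTU004": 1,
    "OTU005": 1,
    "OTU006": 1,
    "OTU007": 1,
    "OTU008": 1,
    "OTU009": 1,
    "OTU010": 1,
    "OTU011": 1,
    "OTU012": 1,
    "OTU013": 1,
    "OTU014": 1,
    "OTU015": 1,
    "OTU016": 1,
    "OTU017": 1,
    "OTU018": 1,
    "OTU019": 1,
    "OTU020": 1,
    "OTU021": 1,
    "OTU022": 1,
    "OTU023": 1,
    "OTU024": 1,
    "OTU025": 1,
    "OTU026": 2,
    "OTU027": 2,
    "OTU028": 2,
    "OTU029": 2,
    "OTU030": 2,
    "OTU031": 2,
    "OTU032": 2,
    "OTU033": 2,
    "OTU034": 2,
    "OTU035": 2,
    "OTU036": 2,
    "OTU037": 2,
    "OTU038": 2,
    "OTU039": 2,
    "OTU040": 2,
    "OTU041": 2,
    "OTU042": 2,
    "OTU043": 2,
    "OTU044": 2,
    "OTU045": 2,
    "OTU046": 2,
    "OTU047": 2,
    "OTU048": 2,
    "OTU049": 2,
    "OTU050": 2,
    "OTU051": 3,
    "OTU052": 3,
    "OTU053": 3,
    "OTU054": 3,
    "OTU055": 3,
    "OTU056": 3,
    "OTU057": 3,
    "OTU058": 3,
    "OTU059": 3,
    "OTU060": 3,
    "OTU061": 3,
    "OTU062": 3,
    "OTU063": 3,
    "OTU064": 3,
    "OTU065": 3,
    "OTU066": 3,
    "OTU067": 3,
    "OTU068": 3,
    "OTU069": 3,
    "OTU070": 3,
    "OTU071": 3,
    "OTU072": 3,
    "OTU073": 3,
    "OTU074": 3,
    "OTU075": 3,
    "OTU076": null,
    "OTU077": null,
    "OTU078": null,
    "OTU079": null,
    "OTU080": null,
    "OTU081": null,
    "OTU082": null,
    "OTU083": null,
    "OTU084": null,
    "OTU085": null,
    "OTU086": null,
    "OTU087": null,
    "OTU088": null,
    "OTU089": null,
    "OTU090": null,
    "OTU091": null,
    "OTU092": null,
    "OTU093": null,
    "OTU094": null,
    "OTU095": null,
    "OTU096": null,
    "OTU097": null,
    "OTU098": null,
    "OTU099": null,
    "OTU100": null
  },
  "core_module_id": 1,
  "seed": 42
}
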