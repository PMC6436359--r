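{
  "version": "1.0",
  "offerings": [
    {
      "offering_id": "liquid",
      "description": "20 ml thin liquid (water)"
    },
    {
      "offering_id": "paste",
      "description": "10 ml paste (thickened liquid, pudding consistency)"
    },
    {
      "offering_id": "solid",
      "description": "one unit of solid (salt cracker)"
    }
  ],
  "items": [
    {
      "item_id": "lip_closure",
      "label": "Altered lip closure",
      "phase": "oral",
      "weight": 1,
      "max_total": 3
    },
    {
      "item_id": "labial_discharge",
      "label": "Labial discharge",
      "phase": "oral",
      "weight": 1,
      "max_total": 3
    },
    {
      "item_id": "oral_transit",
      "label": "Prolonged oral transit time",
      "phase": "oral",
      "weight": 2,
      "max_total": 6
    },
    {
      "item_id": "residue",
      "label": "Residue",
      "phase": "oral",
      "weight": 2,
      "max_total": 6
    },
    {
      "item_id": "multiple_deglutition",
      "label": "Multiple deglutition",
      "phase": "pharyngeal",
      "weight": 2,
      "max_total": 6
    },
    {
      "item_id": "larynx_elevation",
      "label": "Reduced larynx elevation",
      "phase": "pharyngeal",
      "weight": 10,
      "max_total": 30
    },
    {
      "item_id": "cervical_auscultation",
      "label": "Altered cervical auscultation",
      "phase": "pharyngeal",
      "weight": 10,
      "max_total": 30
    },
    {
      "item_id": "throat_clearing",
      "label": "Throat clearing",
      "phase": "penetration_aspiration",
      "weight": 10,
      "max_total": 30
    },
    {
      "item_id": "cough",
      "label": "Cough",
      "phase": "penetration_aspiration",
      "weight": 15,
      "max_total": 45
    },
    {
      "item_id": "voice_quality",
      "label": "Change in voice quality",
      "phase": "penetration_aspiration",
      "weight": 15,
      "max_total": 45
    },
    {
      "item_id": "choking",
      "label": "Choking",
      "phase": "penetration_aspiration",
      "weight": 20,
      "max_total": 60
    },
    {
      "item_id": "breathing",
      "label": "Alteration in breathing",
      "phase": "penetration_aspiration",
      "weight": 30,
      "max_total": 90
    }
  ],
  "schemes": {
    "preliminary": {
      "name": "preliminary",
      "levels": ["normal", "functional", "mild", "moderate", "severe"],
      "upper": [2, 15, 35, 60, 354]
    },
    "revised": {
      "name": "revised",
      "levels": ["normal", "functional", "mild", "moderate_severe"],
      "upper": [3, 19, 35, 354]
    }
  }
}
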