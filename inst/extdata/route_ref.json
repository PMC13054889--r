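{
  "schema": "synthreward-route/1",
  "provenance": "fixture: two-step reference route",
  "root": {
    "type": "mol",
    "id": "TARGET-1",
    "stock": "unavailable",
    "children": [
      {
        "type": "reaction",
        "classification": "2.1.10 Carboxylic ester + amine reaction",
        "children": [
          { "type": "mol", "id": "BB-AMINE-1", "stock": "internal" },
          {
            "type": "mol",
            "id": "INT-ESTER-1",
            "stock": "unavailable",
            "children": [
              {
                "type": "reaction",
                "classification": "3.1.2 Chloro Suzuki coupling",
                "children": [
                  { "type": "mol", "id": "BB-BORONIC-1", "stock": "commercial" },
                  { "type": "mol", "id": "BB-ARYLCL-1", "stock": "internal" }
                ]
              }
            ]
          }
        ]
      }
    ]
  }
}
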