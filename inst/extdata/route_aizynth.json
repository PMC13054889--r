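{
  "type": "mol",
  "smiles": "CCOC(=O)c1ccc(N)cc1",
  "in_stock": false,
  "children": [
    {
      "type": "reaction",
      "metadata": {
        "classification": "2.1.10 Carboxylic ester + amine reaction",
        "policy_probability": 0.42,
        "template_hash": "ignored-by-parser"
      },
      "children": [
        { "type": "mol", "smiles": "CCO", "in_stock": true },
        { "type": "mol", "smiles": "Nc1ccc(C(=O)O)cc1", "in_stock": true }
      ]
    }
  ]
}
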