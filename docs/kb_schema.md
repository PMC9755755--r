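# Knowledgebase JSON schema

A single JSON document with three arrays. All ids are strings and must be
unique within their section; every cross-reference must resolve.

```json
{
  "entities": [
    {
      "id": "E_P10001",
      "kind": "protein",            // protein | chemical | complex | entity_set
      "accession": "P10001",        // UniProt-style (protein) or ChEBI-style
                                    // (chemical); empty for complex/entity_set
      "name": "GENE1",
      "components": []              // entity ids; complex members or set
                                    // members; empty for protein/chemical
    }
  ],
  "reactions": [
    {
      "id": "RX001",
      "name": "A binds B",
      "inputs": ["E_P10001", "E_P10002"],
      "outputs": ["CPLX01"],
      "catalysts": [],
      "regulators": []
    }
  ],
  "pathways": [
    {
      "id": "PW01",
      "name": "Pathway 1",
      "reaction_ids": ["RX001"],
      "child_pathway_ids": [],
      "parent_pathway_id": ""       // empty string marks a top-level pathway
    }
  ]
}
```

Constraints enforced on load:

- `components` is empty iff `kind` is `protein` or `chemical`, non-empty for
  `complex` and `entity_set`;
- complex / entity-set composition is acyclic;
- the pathway hierarchy is a forest (parent links acyclic, and a parent must
  list the child in `child_pathway_ids`);
- every referenced entity, reaction and pathway id exists.

Semantics: members of a `complex` are physically together; members of an
`entity_set` are alternatives (set members never interact among themselves).
Currency metabolites are ordinary `chemical` entities recognized by display
`name` (ATP, ADP, Pi, H2O, GTP, GDP, CO2, H+) when the reaction network is
built.
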