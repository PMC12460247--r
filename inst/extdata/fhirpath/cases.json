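{
  "comment": "FHIRPath case suite: every supported function and operator appears in at least one case. Expected collections were enumerated by hand against the fixture Patient resource before being committed. `input` names a fixture instance (or null for literal-only cases).",
  "cases": [
    {"name": "integer addition", "expression": "1 + 2", "input": null, "expected": [3]},
    {"name": "parenthesized arithmetic", "expression": "(1 + 2) * 3", "input": null, "expected": [9]},
    {"name": "integer division", "expression": "7 div 2", "input": null, "expected": [3]},
    {"name": "modulo", "expression": "7 mod 2", "input": null, "expected": [1]},
    {"name": "decimal division", "expression": "10 / 4", "input": null, "expected": [2.5]},
    {"name": "decimal addition", "expression": "2.5 + 0.5", "input": null, "expected": [3]},
    {"name": "unary minus", "expression": "-3 + 5", "input": null, "expected": [2]},
    {"name": "subtraction", "expression": "5 - 2", "input": null, "expected": [3]},
    {"name": "equality", "expression": "1 = 1", "input": null, "expected": [true]},
    {"name": "inequality", "expression": "1 != 2", "input": null, "expected": [true]},
    {"name": "greater than", "expression": "3 > 2", "input": null, "expected": [true]},
    {"name": "greater or equal false", "expression": "2 >= 3", "input": null, "expected": [false]},
    {"name": "less or equal", "expression": "2 <= 2", "input": null, "expected": [true]},
    {"name": "string comparison", "expression": "'abc' < 'abd'", "input": null, "expected": [true]},
    {"name": "string plus", "expression": "'a' + 'b'", "input": null, "expected": ["ab"]},
    {"name": "string concat operator", "expression": "'a' & 'b'", "input": null, "expected": ["ab"]},
    {"name": "and", "expression": "true and false", "input": null, "expected": [false]},
    {"name": "or", "expression": "true or false", "input": null, "expected": [true]},
    {"name": "xor", "expression": "true xor true", "input": null, "expected": [false]},
    {"name": "implies", "expression": "false implies true", "input": null, "expected": [true]},
    {"name": "grouped or", "expression": "(1 = 2) or true", "input": null, "expected": [true]},
    {"name": "comparison chain", "expression": "1 < 2 and 2 < 3", "input": null, "expected": [true]},
    {"name": "contains", "expression": "'hello'.contains('ell')", "input": null, "expected": [true]},
    {"name": "startsWith", "expression": "'hello'.startsWith('he')", "input": null, "expected": [true]},
    {"name": "substring from", "expression": "'hello'.substring(1)", "input": null, "expected": ["ello"]},
    {"name": "substring range", "expression": "'hello'.substring(1, 3)", "input": null, "expected": ["ell"]},
    {"name": "substring out of range", "expression": "'hello'.substring(99)", "input": null, "expected": []},
    {"name": "toString on integer", "expression": "123.toString()", "input": null, "expected": ["123"]},
    {"name": "toInteger", "expression": "'42'.toInteger()", "input": null, "expected": [42]},
    {"name": "toInteger failure is empty", "expression": "'x1'.toInteger()", "input": null, "expected": []},
    {"name": "toString on boolean", "expression": "true.toString()", "input": null, "expected": ["true"]},
    {"name": "count", "expression": "name.count()", "input": "patient", "expected": [2]},
    {"name": "exists", "expression": "name.exists()", "input": "patient", "expected": [true]},
    {"name": "empty false", "expression": "name.empty()", "input": "patient", "expected": [false]},
    {"name": "first then navigate", "expression": "name.first().family", "input": "patient", "expected": ["Muster"]},
    {"name": "last then navigate", "expression": "name.last().given", "input": "patient", "expected": ["Anni"]},
    {"name": "flattening navigation", "expression": "name.given", "input": "patient", "expected": ["Anna", "Maria", "Anni"]},
    {"name": "indexers", "expression": "name[0].given[1]", "input": "patient", "expected": ["Maria"]},
    {"name": "out-of-range indexer", "expression": "name[5].family", "input": "patient", "expected": []},
    {"name": "where filter", "expression": "name.where(use = 'official').family", "input": "patient", "expected": ["Muster"]},
    {"name": "where first count", "expression": "name.where(use = 'official').first().given.count()", "input": "patient", "expected": [2]},
    {"name": "exists with criteria", "expression": "name.exists(use = 'nickname')", "input": "patient", "expected": [true]},
    {"name": "where no match empty", "expression": "name.where(use = 'x').empty()", "input": "patient", "expected": [true]},
    {"name": "select", "expression": "name.select(given.first())", "input": "patient", "expected": ["Anna", "Anni"]},
    {"name": "date element", "expression": "birthDate", "input": "patient", "expected": ["1980-04-12"]},
    {"name": "boolean element", "expression": "active", "input": "patient", "expected": [true]},
    {"name": "not", "expression": "active.not()", "input": "patient", "expected": [false]},
    {"name": "nested navigation", "expression": "identifier.value", "input": "patient", "expected": ["123"]},
    {"name": "count comparison", "expression": "name.given.count() = 3", "input": "patient", "expected": [true]},
    {"name": "unknown element empty", "expression": "unknown.empty()", "input": "patient", "expected": [true]},
    {"name": "iif true branch", "expression": "iif(active, 'yes', 'no')", "input": "patient", "expected": ["yes"]},
    {"name": "iif false branch", "expression": "iif(name.count() > 5, 'many', 'few')", "input": "patient", "expected": ["few"]},
    {"name": "is Date", "expression": "birthDate is Date", "input": "patient", "expected": [true]},
    {"name": "is model type", "expression": "name.first() is HumanName", "input": "patient", "expected": [true]},
    {"name": "as model type", "expression": "(name.first() as HumanName).family", "input": "patient", "expected": ["Muster"]},
    {"name": "is Boolean", "expression": "active is Boolean", "input": "patient", "expected": [true]},
    {"name": "now constant in context", "expression": "now() = now()", "input": null, "expected": [true]},
    {"name": "today constant in context", "expression": "today() = today()", "input": null, "expected": [true]},
    {"name": "union deduplicates", "expression": "name.given | name.given", "input": "patient", "expected": ["Anna", "Maria", "Anni"]},
    {"name": "conversion then arithmetic", "expression": "identifier.value.toInteger() + 1", "input": "patient", "expected": [124]},
    {"name": "date literals compare", "expression": "@2020-01-01 < @2021-01-01", "input": null, "expected": [true]},
    {"name": "this in criteria", "expression": "name.where($this.use = 'official').count()", "input": "patient", "expected": [1]},
    {"name": "external variable", "expression": "%v + 1", "input": null, "variables": {"v": 5}, "expected": [6]},
    {"name": "iif without else", "expression": "iif(false, 'a')", "input": null, "expected": []},
    {"name": "first on flattened", "expression": "name.given.first()", "input": "patient", "expected": ["Anna"]}
  ]
}
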