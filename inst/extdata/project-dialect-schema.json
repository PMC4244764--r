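{
  "dialect": "1.0",
  "description": "Machine-readable description of the project-definition vocabulary, in its XML form and the field-for-field JSON mirror. Unknown attributes and elements are legal everywhere and must be preserved by processors.",
  "xml": {
    "project": {
      "attributes": {
        "dialect": "dialect version, required",
        "name": "unique project identifier, required",
        "title": "displayed title",
        "version": "project definition version",
        "visibility": "public | private"
      },
      "children": ["form+"]
    },
    "form": {
      "attributes": {
        "id": "unique form id, required",
        "title": "displayed title, required",
        "key": "field id of the key field, or AUTO",
        "level": "hierarchy position 1..n (hierarchy forms only)",
        "branch-of": "host form id (branch forms only)",
        "branch-at": "host branch_trigger field id (branch forms only)"
      },
      "children": ["field*"]
    },
    "field": {
      "attributes": {
        "id": "unique field id within the form, required",
        "type": "text | long_text | dropdown | checkbox | radio | location | image | video | audio | barcode | branch_trigger, required",
        "label": "question text shown to the data gatherer, required",
        "required": "true when an answer is mandatory",
        "numeric": "integer | decimal",
        "min": "minimum accepted numeric value",
        "max": "maximum accepted numeric value",
        "date": "date/time format such as dd/mm/yyyy or mm:ss",
        "regex": "regular expression the raw input must match",
        "double-entry": "true when the value must be entered twice",
        "chartable": "true when answer counts are charted (choice fields)"
      },
      "children": ["choice*", "jump*"]
    },
    "choice": {
      "attributes": {
        "name": "text shown to the user, required",
        "value": "stored value, required"
      }
    },
    "jump": {
      "attributes": {
        "when": "comma-separated trigger choice values (OR), required",
        "to": "destination field id later in the form, or END, required"
      }
    }
  },
  "json_mirror": {
    "project": ["dialect", "name", "title", "version", "visibility", "forms[]"],
    "form": ["id", "title", "key", "level | branch_of + branch_at", "fields[]"],
    "field": ["id", "type", "label", "required", "numeric", "min", "max", "date", "regex", "double_entry", "chartable", "choices[]", "jumps[]"],
    "choice": ["name", "value"],
    "jump": ["when[]", "to"]
  },
  "entries_export": {
    "entries": {
      "attributes": {"project": "project name", "dialect": "dialect version", "form": "root form id"},
      "children": ["entry*"]
    },
    "entry": {
      "attributes": {
        "form": "form id", "id": "globally unique entry id",
        "key": "entry key value", "parent": "parent entry key (absent at top level)",
        "created": "creation time, UTC epoch milliseconds", "device": "device id"
      },
      "children": ["value*", "branch*", "entry* (next hierarchy level)"]
    },
    "value": {
      "attributes": {
        "field": "field id",
        "lat,lon,alt,accuracy": "location answers",
        "uri,thumbnail": "media answers"
      },
      "content": "answer text (checkbox answers as <v> children)"
    },
    "branch": {
      "attributes": {"field": "host branch_trigger field id"},
      "children": ["entry* (branch form entries)"]
    }
  }
}
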