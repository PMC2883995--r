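{"word":"light","synonyms":["bright","shiny"],"antonyms":["dark","dim"]}
{"word":"bright","synonyms":["shiny","glowing"],"antonyms":["dim"]}
{"word":"shiny","synonyms":["glowing"],"antonyms":["murky"]}
{"word":"glowing","synonyms":["light"],"antonyms":["shadowy"]}
{"word":"dark","synonyms":["dim","murky"],"antonyms":["bright"]}
{"word":"dim","synonyms":["murky","shadowy"],"antonyms":["shiny"]}
{"word":"murky","synonyms":["shadowy"],"antonyms":["glowing"]}
{"word":"shadowy","synonyms":["dark"],"antonyms":["light"]}
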