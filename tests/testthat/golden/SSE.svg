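<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="420" height="420" viewBox="0 0 420 420" font-family="Helvetica, Arial, sans-serif">
  <title>SSE</title>
  <path d="M 210.000 39.900 A 170.100 170.100 0 0 1 309.982 72.386 L 259.374 142.043 A 84.000 84.000 0 0 0 210.000 126.000 Z" fill="#F9A825" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 309.982 72.386 A 170.100 170.100 0 0 1 371.775 157.436 L 289.889 184.043 A 84.000 84.000 0 0 0 259.374 142.043 Z" fill="#C62828" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 371.775 157.436 A 170.100 170.100 0 0 1 371.775 262.564 L 289.889 235.957 A 84.000 84.000 0 0 0 289.889 184.043 Z" fill="#2E7D32" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 371.775 262.564 A 170.100 170.100 0 0 1 309.982 347.614 L 259.374 277.957 A 84.000 84.000 0 0 0 289.889 235.957 Z" fill="#C62828" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 309.982 347.614 A 170.100 170.100 0 0 1 210.000 380.100 L 210.000 294.000 A 84.000 84.000 0 0 0 259.374 277.957 Z" fill="#2E7D32" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 210.000 380.100 A 170.100 170.100 0 0 1 110.018 347.614 L 160.626 277.957 A 84.000 84.000 0 0 0 210.000 294.000 Z" fill="#2E7D32" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 110.018 347.614 A 170.100 170.100 0 0 1 48.225 262.564 L 130.111 235.957 A 84.000 84.000 0 0 0 160.626 277.957 Z" fill="#C62828" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 48.225 262.564 A 170.100 170.100 0 0 1 48.225 157.436 L 130.111 184.043 A 84.000 84.000 0 0 0 130.111 235.957 Z" fill="#2E7D32" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 48.225 157.436 A 170.100 170.100 0 0 1 110.018 72.386 L 160.626 142.043 A 84.000 84.000 0 0 0 130.111 184.043 Z" fill="#F9A825" stroke="#FFFFFF" stroke-width="1.5"/>
  <path d="M 110.018 72.386 A 170.100 170.100 0 0 1 210.000 39.900 L 210.000 126.000 A 84.000 84.000 0 0 0 160.626 142.043 Z" fill="#C62828" stroke="#FFFFFF" stroke-width="1.5"/>
  <line x1="210.000" y1="126.000" x2="210.000" y2="39.900" stroke="#FFFFFF" stroke-width="4"/>
  <line x1="259.374" y1="277.957" x2="309.982" y2="347.614" stroke="#FFFFFF" stroke-width="4"/>
  <line x1="130.111" y1="184.043" x2="48.225" y2="157.436" stroke="#FFFFFF" stroke-width="4"/>
  <text x="249.261" y="89.168" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Solvent EI</text>
  <text x="312.786" y="135.322" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Feed T</text>
  <text x="337.050" y="210.000" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Removal</text>
  <text x="312.786" y="284.678" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Actives</text>
  <text x="249.261" y="330.832" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Energy</text>
  <text x="170.739" y="330.832" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Print T</text>
  <text x="107.214" y="284.678" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Time</text>
  <text x="82.950" y="210.000" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Waste</text>
  <text x="107.214" y="135.322" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Cure</text>
  <text x="170.739" y="89.168" text-anchor="middle" dominant-baseline="middle" font-size="10.920" fill="#FFFFFF">Cure t</text>
  <circle cx="210.000" cy="210.000" r="69.300" fill="#F9A825" stroke="#FFFFFF" stroke-width="2"/>
  <text x="210.000" y="210.000" text-anchor="middle" dominant-baseline="middle" font-size="46.200" font-weight="bold" fill="#FFFFFF">5.75</text>
</svg>
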